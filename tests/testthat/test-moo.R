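# NSGA machinery: repair, dominance, sorting, crowding, reference points,
# niching, termination, the generational loop, and backward elimination.

test_that("repair sets exactly one uniform gene on all-zero chromosomes", {
  expect_identical(repair(c(0L, 1L, 0L)), c(0L, 1L, 0L))
  eegselect:::with_seed(1, {
    fixed <- repair(rep(0L, 22))
    expect_equal(sum(fixed), 1L)
  })
  n_trials <- 10000L
  picks <- eegselect:::with_seed(42, vapply(seq_len(n_trials), function(i) {
    which(repair(rep(0L, 22)) == 1L)
  }, 0L))
  counts <- tabulate(picks, 22)
  # multinomial bound oracle: chi-squared GOF against uniform, plus a
  # family-wise per-gene bound (22 simultaneous bins)
  gof <- chisq.test(counts, p = rep(1 / 22, 22))
  expect_gt(gof$p.value, 1e-3)
  p <- 1 / 22
  z_fw <- qnorm(1 - (1 - pnorm(3)) / 22)   # 3-sigma rate, Sidak-adjusted
  expect_true(all(abs(counts / n_trials - p) <=
                  z_fw * sqrt(p * (1 - p) / n_trials)))
})

test_that("dominance follows the (max Acc, min No) partial order", {
  expect_true(dominates(list(acc = 0.9, no = 3), list(acc = 0.8, no = 5)))
  expect_false(dominates(list(acc = 0.9, no = 3), list(acc = 0.9, no = 3)))
  expect_false(dominates(list(acc = 0.9, no = 5), list(acc = 0.8, no = 3)))
  expect_false(dominates(list(acc = 0.8, no = 3), list(acc = 0.9, no = 5)))
  expect_true(dominates(list(acc = 0.9, no = 3), list(acc = 0.9, no = 4)))
})

test_that("fast non-dominated sort matches the brute-force oracle", {
  expect_identical(fast_nondominated_sort(data.frame(acc = 0.5, no = 3)),
                   list(1L))
  chain <- data.frame(acc = c(0.9, 0.8, 0.7), no = c(1, 1, 1))
  expect_identical(fast_nondominated_sort(chain), list(1L, 2L, 3L))
  for (inst in 1:100) {
    pts <- eegselect:::with_seed(inst, data.frame(
      acc = round(runif(50), 2), no = sample.int(10, 50, replace = TRUE)))
    fast <- fast_nondominated_sort(pts)
    slow <- brute_force_fronts(pts$acc, pts$no)
    expect_identical(lapply(fast, sort), slow)
  }
})

test_that("crowding distance: boundaries Inf, spacing 2.0, duplicates 0", {
  expect_identical(crowding_distance(data.frame(a = c(1, 2), b = c(2, 1))),
                   c(Inf, Inf))
  three <- data.frame(a = c(0, 1, 2), b = c(2, 1, 0))
  expect_identical(crowding_distance(three), c(Inf, 2, Inf))
  dup <- data.frame(a = c(0, 1, 1, 1, 2), b = c(2, 1, 1, 1, 0))
  cd <- crowding_distance(dup)
  expect_true(any(cd[2:4] == 0))       # duplicated interior points
})

test_that("Das-Dennis points lie on the simplex with the exact count", {
  pts <- das_dennis_points(3, 4)
  expect_equal(nrow(pts), choose(3 + 4 - 1, 4))   # 15
  expect_true(all(abs(rowSums(pts) - 1) < 1e-12))
  apexes <- diag(3)
  for (i in 1:3) {
    expect_true(any(apply(pts, 1, function(r) all(r == apexes[i, ]))))
  }
  pts2 <- das_dennis_points(2, 19)
  expect_equal(nrow(pts2), 20)
})

test_that("reference-line association matches brute-force geometry", {
  ref <- das_dennis_points(2, 9)
  fn <- eegselect:::with_seed(7, matrix(runif(40), ncol = 2))
  asc <- eegselect:::associate_to_refs(fn, ref)
  for (i in seq_len(nrow(fn))) {
    d <- vapply(seq_len(nrow(ref)), function(r) {
      w <- ref[r, ] / sqrt(sum(ref[r, ]^2))
      proj <- sum(fn[i, ] * w)
      sqrt(max(sum(fn[i, ]^2) - proj^2, 0))
    }, 0)
    expect_equal(asc$assoc[i], which.min(d))
    expect_equal(asc$dist[i], min(d))
  }
})

test_that("nsga3_select keeps whole fronts and is elitist", {
  # first front of exactly N mutually non-dominated points + N dominated
  N <- 10
  front <- cbind(seq(0, 1, length.out = N), seq(1, 0, length.out = N))
  dominated <- front + 0.5
  pool <- rbind(front, dominated)
  ref <- das_dennis_points(2, N - 1)
  surv <- eegselect:::with_seed(1, nsga3_select(pool, ref, N))
  expect_setequal(surv, seq_len(N))
  # elitism for random pools: front 1 always survives when it fits
  for (s in 1:5) {
    pool <- eegselect:::with_seed(s, matrix(runif(60), ncol = 2))
    f1 <- eegselect:::nds_min(pool)[[1]]
    if (length(f1) <= N) {
      surv <- eegselect:::with_seed(s, nsga3_select(pool, ref, N))
      expect_true(all(f1 %in% surv))
    }
  }
  expect_error(nsga3_select(front, ref, 2 * N), "pool smaller")
})

test_that("termination triggers only on a stable matched front", {
  snapA <- data.frame(no = c(1, 3), acc = c(0.8, 0.9))
  snapB <- data.frame(no = c(1, 3), acc = c(0.81, 0.9))
  expect_false(termination_check(list(snapA), 1e-4))
  expect_true(termination_check(list(snapA, snapA), 1e-4))
  expect_false(termination_check(list(snapA, snapB), 1e-4))
  snapC <- data.frame(no = c(1, 2, 3), acc = c(0.8, 0.85, 0.9))
  expect_false(termination_check(list(snapA, snapC), 1e-4))  # new No => 1
  expect_false(termination_check(list(snapA, snapA), 0))     # unreachable
})

test_that("run_nsga is deterministic and its archive is sound", {
  stub <- make_lookup_fitness(6, seed = 11)
  cfg <- ga_config(seed = 5, max_generations = 40)
  r1 <- run_nsga("II", evaluator = stub, n_chan = 6, config = cfg)
  r2 <- run_nsga("II", evaluator = stub, n_chan = 6, config = cfg)
  expect_identical(r1$archive, r2$archive)
  expect_identical(r1$history, r2$history)
  # no archive entry dominates another
  arch <- r1$archive
  for (i in seq_len(nrow(arch))) {
    for (j in seq_len(nrow(arch))) {
      if (i != j) {
        expect_false(dominates(list(acc = arch$acc[i], no = arch$no[i]),
                               list(acc = arch$acc[j], no = arch$no[j])))
      }
    }
  }
  # archived subsets reproduce their accuracy (memoization consistency)
  for (i in seq_len(nrow(arch))) {
    expect_identical(stub(arch$subset[[i]])$accuracy, arch$acc[i])
    expect_equal(length(arch$subset[[i]]), arch$no[i])
  }
})

test_that("the archive is the running best per subset size (elitism)", {
  C <- 6
  inner <- make_lookup_fitness(C, seed = 13)
  seen <- new.env(parent = emptyenv())
  recorder <- function(subset) {
    sc <- inner(subset)
    key <- as.character(length(subset))
    seen[[key]] <- max(sc$accuracy, seen[[key]] %||% -Inf)
    sc
  }
  attr(recorder, "n_channels") <- C
  r <- run_nsga("III", evaluator = recorder, n_chan = C,
                config = ga_config(seed = 2, max_generations = 30))
  # every evaluated size is represented by its best accuracy before pruning
  for (i in seq_len(nrow(r$archive))) {
    expect_equal(r$archive$acc[i], seen[[as.character(r$archive$no[i])]])
  }
  # distinct evaluations bounded by the search-space and budget sizes
  expect_lte(r$n_evaluations,
             min(2^C - 1, 20 * (r$n_generations + 1)))
})

test_that("backward elimination counts calls and nests incumbents", {
  calls <- 0L
  stub <- function(subset) {
    calls <<- calls + 1L
    list(accuracy = 0.5)               # all ties
  }
  attr(stub, "n_channels") <- 3L
  path <- backward_elimination(evaluator = stub, n_chan = 3)
  expect_equal(attr(path, "n_calls"), 6L)        # 1 + 3 + 2
  expect_equal(path$no, c(3L, 2L, 1L))
  # ties remove the lowest-index channel first
  expect_identical(path$subset[[2]], c(2L, 3L))
  expect_identical(path$subset[[3]], 3L)
  # incumbents are nested
  expect_true(all(path$subset[[3]] %in% path$subset[[2]]))
  expect_true(all(path$subset[[2]] %in% path$subset[[1]]))
})

test_that("backward elimination recovers the planted channel", {
  hits <- vapply(1:5, function(s) {
    ft <- planted_table(seed = s, n_per_class = 20, snr = 3)
    path <- backward_elimination(ft, portfolio = portfolio_spec(n_trees = 25),
                                 k = 10, seed = 1)
    identical(path$subset[[nrow(path)]], 2L)     # channel 2 is informative
  }, TRUE)
  expect_gte(sum(hits), 4)
})
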