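# Channel-subset search: chromosome encoding, from-scratch NSGA-II and
# NSGA-III over the bi-objective fitness (maximize CV accuracy, minimize
# channel count), with the every-5th-generation objective-space tolerance
# termination rule and a Pareto archive of the best solution per subset
# size ever encountered.

#' GA configuration
#'
#' @param population_size Population size N (even; default 20).
#' @param max_generations Generation ceiling (default 500).
#' @param tolerance Objective-space tolerance for early termination
#'   (default 1e-4); 0 makes the criterion unreachable.
#' @param check_interval Generations between termination checks (default 5).
#' @param crossover_prob Two-point crossover probability (default 0.9).
#' @param mutation_prob Per-gene bit-flip probability; `NULL` means `1/C`.
#' @param seed Integer seed for all GA randomness.
#' @param n_objectives Number of objectives M (2: accuracy, channel count).
#' @param reference_partitions Das-Dennis partitions p for NSGA-III;
#'   `NULL` means `population_size - 1` (point count = population size for
#'   M = 2).
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 20, max_generations = 500,
                      tolerance = 1e-4, check_interval = 5,
                      crossover_prob = 0.9, mutation_prob = NULL,
                      seed = 1, n_objectives = 2,
                      reference_partitions = NULL) {
  population_size <- assert_count(population_size, "population_size",
                                  min = 2L)
  if (population_size %% 2L != 0L) {
    stop("population_size must be even", call. = FALSE)
  }
  tolerance <- assert_number(tolerance, "tolerance", min = 0)
  structure(list(
    population_size = population_size,
    max_generations = assert_count(max_generations, "max_generations"),
    tolerance = tolerance,
    check_interval = assert_count(check_interval, "check_interval"),
    crossover_prob = assert_number(crossover_prob, "crossover_prob", 0),
    mutation_prob = mutation_prob,
    seed = seed,
    n_objectives = assert_count(n_objectives, "n_objectives", min = 2L),
    reference_partitions = reference_partitions
  ), class = "ga_config")
}

#' Repair an all-zero chromosome
#'
#' An empty channel subset is meaningless; if no gene is set, exactly one
#' uniformly chosen gene is switched on. Non-zero chromosomes pass through
#' unchanged. Uses the current RNG stream.
#'
#' @param chrom Binary integer vector (genes).
#' @return Repaired chromosome.
#' @export
repair <- function(chrom) {
  if (sum(chrom) == 0L) {
    chrom[sample.int(length(chrom), 1L)] <- 1L
  }
  chrom
}

#' Pareto dominance for (accuracy, channel count) fitness
#'
#' `a` dominates `b` iff `a` has accuracy >= and channel count <= `b`'s,
#' with at least one strict inequality.
#'
#' @param a,b Fitness values: lists or vectors with elements `acc` and `no`.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  (a[["acc"]] >= b[["acc"]] && a[["no"]] <= b[["no"]]) &&
    (a[["acc"]] > b[["acc"]] || a[["no"]] < b[["no"]])
}

# Fast non-dominated sort on a minimization objective matrix (rows =
# solutions). Deb's O(MN^2) bookkeeping. Returns list of index vectors.
nds_min <- function(mat) {
  n <- nrow(mat)
  if (n == 0L) return(list())
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      le <- all(mat[i, ] <= mat[j, ])
      lt <- any(mat[i, ] < mat[j, ])
      if (le && lt) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (all(mat[j, ] <= mat[i, ]) && any(mat[j, ] < mat[i, ])) {
        dom_count[i] <- dom_count[i] + 1L
      }
    }
  }
  fronts <- list()
  current <- which(dom_count == 0L)
  while (length(current) > 0L) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(unique(nxt))
  }
  fronts
}

#' Fast non-dominated sorting
#'
#' Partitions fitness values into Pareto fronts: front 1 is the
#' non-dominated set, front i+1 is non-dominated after removing fronts
#' <= i.
#'
#' @param fitnesses data.frame or matrix with columns `acc` (maximized)
#'   and `no` (minimized), one row per solution.
#' @return List of integer index vectors (fronts, best first).
#' @export
fast_nondominated_sort <- function(fitnesses) {
  fitnesses <- as.data.frame(fitnesses)
  nds_min(cbind(-fitnesses$acc, fitnesses$no))
}

#' Crowding distance within one front
#'
#' Per objective, members are sorted; boundary members get `Inf`, interior
#' members accumulate range-normalized neighbour gaps. Duplicated interior
#' points get 0.
#'
#' @param front_fitnesses Matrix or data.frame of objective values (rows =
#'   front members, any orientation: distances only use spacing).
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(front_fitnesses) {
  mat <- as.matrix(as.data.frame(front_fitnesses))
  m <- nrow(mat)
  if (m == 0L) return(numeric(0))
  if (m <= 2L) return(rep(Inf, m))
  dist <- numeric(m)
  for (j in seq_len(ncol(mat))) {
    ord <- order(mat[, j])
    rng <- mat[ord[m], j] - mat[ord[1L], j]
    dist[ord[1L]] <- Inf
    dist[ord[m]] <- Inf
    if (rng <= 0) next
    for (i in 2:(m - 1L)) {
      dist[ord[i]] <- dist[ord[i]] +
        (mat[ord[i + 1L], j] - mat[ord[i - 1L], j]) / rng
    }
  }
  dist
}

#' Das-Dennis structured reference points
#'
#' All points on the unit simplex with coordinates in `{0, 1/p, ..., 1}`
#' summing to one: `choose(M + p - 1, p)` points on the hyper-plane equally
#' inclined to all objective axes with intercept 1 on each (for M = 3, the
#' triangle with apexes (1,0,0), (0,1,0), (0,0,1)).
#'
#' @param M Number of objectives (>= 2).
#' @param p Number of partitions (>= 1).
#' @return Matrix, one reference point per row.
#' @export
das_dennis_points <- function(M, p) {
  M <- assert_count(M, "M", min = 2L)
  p <- assert_count(p, "p", min = 1L)
  recur <- function(m, left) {
    if (m == 1L) return(matrix(left, ncol = 1L))
    do.call(rbind, lapply(0:left, function(i) {
      cbind(i, recur(m - 1L, left - i))
    }))
  }
  pts <- recur(M, p) / p
  dimnames(pts) <- NULL
  pts
}

# Perpendicular distance from each point (rows of fn) to each reference
# line through the origin (rows of ref). Returns list(assoc, dist).
associate_to_refs <- function(fn, ref) {
  w <- ref / sqrt(rowSums(ref^2))
  proj <- fn %*% t(w)                      # n x R projections
  n <- nrow(fn)
  d <- matrix(0, n, nrow(ref))
  norm2 <- rowSums(fn^2)
  d <- sqrt(pmax(outer(norm2, rep(1, nrow(ref))) - proj^2, 0))
  assoc <- max.col(-d, ties.method = "first")
  list(assoc = assoc, dist = d[cbind(seq_len(n), assoc)])
}

#' NSGA-III environmental selection
#'
#' Admits whole fronts while they fit; the splitting front is resolved by
#' normalizing objectives (ideal point, ASF extreme points, intercepts),
#' associating members to their minimum-perpendicular-distance reference
#' line, and filling the least-crowded niches (Deb & Jain niching). Uses
#' the current RNG stream for niche tie-breaks.
#'
#' @param fitnesses Matrix of minimization objectives, one row per pool
#'   member (parents + offspring).
#' @param ref_points Reference points from [das_dennis_points()].
#' @param N Number of survivors.
#' @return Integer indices of survivors.
#' @export
nsga3_select <- function(fitnesses, ref_points, N) {
  mat <- as.matrix(fitnesses)
  if (nrow(mat) < N) stop("pool smaller than N", call. = FALSE)
  fronts <- nds_min(mat)
  chosen <- integer(0)
  l <- 0L
  for (f in seq_along(fronts)) {
    if (length(chosen) + length(fronts[[f]]) <= N) {
      chosen <- c(chosen, fronts[[f]])
      l <- f
      if (length(chosen) == N) return(chosen)
    } else {
      l <- f
      break
    }
  }
  split_front <- fronts[[l]]
  S <- c(chosen, split_front)
  sub <- mat[S, , drop = FALSE]
  M <- ncol(sub)
  ideal <- apply(sub, 2L, min)
  ft <- sweep(sub, 2L, ideal)
  # extreme points by achievement scalarizing function along each axis
  extremes <- vapply(seq_len(M), function(j) {
    w <- rep(1e-6, M); w[j] <- 1
    which.min(apply(sweep(ft, 2L, w, "/"), 1L, max))
  }, 0L)
  E <- ft[extremes, , drop = FALSE]
  intercepts <- apply(ft, 2L, max)
  if (abs(det(E)) > 1e-12) {
    a <- tryCatch(solve(E, rep(1, M)), error = function(e) NULL)
    if (!is.null(a) && all(a > 1e-12)) intercepts <- 1 / a
  }
  intercepts[intercepts < 1e-12] <- 1
  fn <- sweep(ft, 2L, intercepts, "/")
  asc <- associate_to_refs(fn, as.matrix(ref_points))
  n_ref <- nrow(as.matrix(ref_points))
  rho <- tabulate(asc$assoc[seq_along(chosen)], nbins = n_ref)
  pending <- seq_along(split_front) + length(chosen)  # rows of `sub`
  K <- N - length(chosen)
  picked <- integer(0)
  active <- rep(TRUE, n_ref)
  while (K > 0L) {
    avail_refs <- which(active)
    if (length(avail_refs) == 0L) {  # all niches exhausted: fill arbitrarily
      left <- setdiff(pending, picked)
      picked <- c(picked, left[seq_len(K)])
      break
    }
    jmin <- avail_refs[rho[avail_refs] == min(rho[avail_refs])]
    jbar <- if (length(jmin) > 1L) jmin[sample.int(length(jmin), 1L)] else jmin
    members <- setdiff(pending[asc$assoc[pending] == jbar], picked)
    if (length(members) == 0L) {
      active[jbar] <- FALSE
      next
    }
    sel <- if (rho[jbar] == 0L) {
      members[which.min(asc$dist[members])]
    } else if (length(members) > 1L) {
      members[sample.int(length(members), 1L)]
    } else members
    picked <- c(picked, sel)
    rho[jbar] <- rho[jbar] + 1L
    K <- K - 1L
  }
  c(chosen, split_front[picked - length(chosen)])
}

#' Front-movement termination check
#'
#' The archive front is snapshotted at every `check_interval`-th
#' generation; termination triggers when, between the two most recent
#' snapshots, the maximum absolute change over both normalized objectives
#' is below `tolerance`. Fronts are matched by channel count; a channel
#' count present in only one snapshot counts as change 1. The first check
#' (no previous snapshot) never terminates.
#'
#' @param front_history List of snapshots (data.frames with columns `no`,
#'   `acc`), most recent last.
#' @param tolerance Non-negative tolerance; 0 is unreachable.
#' @param check_interval Unused in the comparison (documented cadence).
#' @return Logical: stop now?
#' @export
termination_check <- function(front_history, tolerance,
                              check_interval = 5) {
  h <- length(front_history)
  if (h < 2L) return(FALSE)
  prev <- front_history[[h - 1L]]
  cur <- front_history[[h]]
  nos <- union(prev$no, cur$no)
  changes <- vapply(nos, function(v) {
    i <- match(v, prev$no)
    j <- match(v, cur$no)
    if (is.na(i) || is.na(j)) return(1)
    abs(prev$acc[i] - cur$acc[j])
  }, 0)
  max(changes) < tolerance
}

# --- archive helpers ---------------------------------------------------

archive_update <- function(archive, acc, no, subset, classifier_id,
                           sensitivity, specificity, gen) {
  key <- as.character(no)
  cur <- archive[[key]]
  if (is.null(cur) || acc > cur$acc) {
    archive[[key]] <- list(acc = acc, no = no, subset = subset,
                           classifier_id = classifier_id,
                           sensitivity = sensitivity,
                           specificity = specificity,
                           generation_found = gen)
  }
  invisible(archive)
}

# Best-accuracy-per-size entries, pruned to the non-dominated set,
# ascending by channel count.
archive_front <- function(archive) {
  keys <- ls(archive)
  if (length(keys) == 0L) {
    return(data.frame(no = integer(0), acc = numeric(0)))
  }
  entries <- lapply(keys, function(k) archive[[k]])
  no <- vapply(entries, `[[`, 0, "no")
  ord <- order(no)
  entries <- entries[ord]
  best <- -Inf
  keep <- logical(length(entries))
  for (i in seq_along(entries)) {
    if (entries[[i]]$acc > best) {
      keep[i] <- TRUE
      best <- entries[[i]]$acc
    }
  }
  entries <- entries[keep]
  data.frame(
    no = vapply(entries, `[[`, 0, "no"),
    acc = vapply(entries, `[[`, 0, "acc"),
    sensitivity = vapply(entries, function(e)
      if (is.null(e$sensitivity)) NA_real_ else e$sensitivity, 0),
    specificity = vapply(entries, function(e)
      if (is.null(e$specificity)) NA_real_ else e$specificity, 0),
    classifier = vapply(entries, function(e)
      if (is.null(e$classifier_id)) NA_character_ else e$classifier_id, ""),
    subset = I(lapply(entries, `[[`, "subset")),
    generation_found = vapply(entries, `[[`, 0, "generation_found")
  )
}

# --- genetic operators -------------------------------------------------

two_point_crossover <- function(a, b, prob) {
  C <- length(a)
  if (runif(1) >= prob || C < 2L) return(list(a, b))
  cuts <- sort(sample.int(C - 1L, 2L, replace = TRUE))
  seg <- (cuts[1] + 1L):cuts[2]
  if (cuts[1] == cuts[2]) return(list(a, b))
  a2 <- a; b2 <- b
  a2[seg] <- b[seg]; b2[seg] <- a[seg]
  list(a2, b2)
}

bitflip_mutation <- function(chrom, prob) {
  flip <- runif(length(chrom)) < prob
  chrom[flip] <- 1L - chrom[flip]
  chrom
}

#' Run NSGA-II or NSGA-III channel-subset selection
#'
#' Generational loop with binary tournament mating selection (rank +
#' crowding for NSGA-II; rank for NSGA-III), two-point crossover, per-gene
#' bit-flip mutation, all-zero repair, and memoized fitness evaluation.
#' The archive accumulates the best accuracy observed at every channel
#' count across the whole run; the run stops when the archive front's
#' movement between consecutive checks falls below the tolerance (checked
#' every `check_interval` generations), or at `max_generations`.
#'
#' @param variant `"II"` or `"III"`.
#' @param table A `feature_table`; may be `NULL` when a custom `evaluator`
#'   and `n_chan` are supplied (e.g. stub fitness in tests).
#' @param config A [ga_config()].
#' @param evaluator Function `(subset) -> list(accuracy, ...)`; defaults to
#'   [make_evaluator()] on `table`.
#' @param n_chan Chromosome length; defaults to the table's channel count.
#' @param portfolio,k Passed to [make_evaluator()] when `evaluator` is NULL.
#' @return Object of class `nsga_result`: list with `archive` (data.frame,
#'   one row per channel count, mutually non-dominated), `history`
#'   (per-generation data.frame), `n_generations`, `n_evaluations`
#'   (distinct), `classifier_usage`, `variant`, `config`.
#' @export
run_nsga <- function(variant = c("II", "III"), table = NULL,
                     config = ga_config(), evaluator = NULL,
                     n_chan = NULL, portfolio = portfolio_spec(), k = 10) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "ga_config"))
  if (is.null(evaluator)) {
    if (is.null(table)) stop("need a feature table or an evaluator",
                             call. = FALSE)
    evaluator <- make_evaluator(table, portfolio, k = k, seed = config$seed)
  }
  if (is.null(n_chan)) {
    n_chan <- if (!is.null(table)) n_channels(table)
              else attr(evaluator, "n_channels")
  }
  C <- assert_count(n_chan, "n_chan", min = 2L)
  N <- config$population_size
  pm <- if (is.null(config$mutation_prob)) 1 / C else config$mutation_prob
  ref_points <- NULL
  if (variant == "III") {
    p <- if (is.null(config$reference_partitions)) N - 1L
         else config$reference_partitions
    ref_points <- das_dennis_points(config$n_objectives, p)
  }

  cache <- new.env(parent = emptyenv())
  n_distinct <- 0L
  usage <- c(svm = 0L, knn = 0L, rf = 0L, nb = 0L, other = 0L)
  archive <- new.env(parent = emptyenv())
  gen_now <- 0L

  eval_mask <- function(genes) {
    key <- paste(genes, collapse = "")
    hit <- cache[[key]]
    if (is.null(hit)) {
      subset <- which(genes == 1L)
      score <- evaluator(subset)
      hit <- list(acc = score$accuracy, no = length(subset),
                  score = score)
      cache[[key]] <- hit
      n_distinct <<- n_distinct + 1L
      archive_update(archive, hit$acc, hit$no, subset,
                     score$classifier_id, score$sensitivity,
                     score$specificity, gen_now)
    }
    fam <- hit$score$classifier_family
    if (is.null(fam) || !fam %in% names(usage)) fam <- "other"
    usage[[fam]] <<- usage[[fam]] + 1L
    hit
  }

  history <- vector("list", config$max_generations + 1L)
  snapshots <- list()
  terminated_early <- FALSE

  with_seed(config$seed, {
    pop <- matrix(as.integer(runif(N * C) < 0.5), nrow = N, ncol = C)
    for (i in seq_len(N)) pop[i, ] <- repair(pop[i, ])
    res <- lapply(seq_len(N), function(i) eval_mask(pop[i, ]))
    acc <- vapply(res, `[[`, 0, "acc")
    no <- vapply(res, `[[`, 0, "no")
    history[[1L]] <- data.frame(generation = 0L,
                                best_acc = max(acc),
                                best_no = no[which.max(acc)],
                                evaluations = n_distinct)
    for (gen in seq_len(config$max_generations)) {
      gen_now <- gen
      objs <- cbind(1 - acc, no)           # minimization orientation
      fronts <- nds_min(objs)
      rank <- integer(N)
      crowd <- numeric(N)
      for (f in seq_along(fronts)) {
        rank[fronts[[f]]] <- f
        crowd[fronts[[f]]] <- crowding_distance(objs[fronts[[f]], ,
                                                     drop = FALSE])
      }
      pick_parent <- function() {
        ij <- sample.int(N, 2L)
        i <- ij[1L]; j <- ij[2L]
        if (rank[i] != rank[j]) return(if (rank[i] < rank[j]) i else j)
        if (variant == "II" && crowd[i] != crowd[j]) {
          return(if (crowd[i] > crowd[j]) i else j)
        }
        ij[sample.int(2L, 1L)]
      }
      offspring <- matrix(0L, nrow = N, ncol = C)
      for (pair in seq_len(N / 2L)) {
        pa <- pop[pick_parent(), ]
        pb <- pop[pick_parent(), ]
        kids <- two_point_crossover(pa, pb, config$crossover_prob)
        kids[[1L]] <- repair(bitflip_mutation(kids[[1L]], pm))
        kids[[2L]] <- repair(bitflip_mutation(kids[[2L]], pm))
        offspring[2L * pair - 1L, ] <- kids[[1L]]
        offspring[2L * pair, ] <- kids[[2L]]
      }
      res_off <- lapply(seq_len(N), function(i) eval_mask(offspring[i, ]))
      pool <- rbind(pop, offspring)
      pool_acc <- c(acc, vapply(res_off, `[[`, 0, "acc"))
      pool_no <- c(no, vapply(res_off, `[[`, 0, "no"))
      pool_objs <- cbind(1 - pool_acc, pool_no)
      surv <- if (variant == "II") {
        nsga2_truncate(pool_objs, N)
      } else {
        nsga3_select(pool_objs, ref_points, N)
      }
      pop <- pool[surv, , drop = FALSE]
      acc <- pool_acc[surv]
      no <- pool_no[surv]
      history[[gen + 1L]] <- data.frame(generation = gen,
                                        best_acc = max(acc),
                                        best_no = no[which.max(acc)],
                                        evaluations = n_distinct)
      if (gen %% config$check_interval == 0L) {
        snapshots[[length(snapshots) + 1L]] <- archive_front(archive)
        if (termination_check(snapshots, config$tolerance,
                              config$check_interval)) {
          terminated_early <- TRUE
          break
        }
      }
    }
  })

  history <- do.call(rbind, history[!vapply(history, is.null, TRUE)])
  front <- archive_front(archive)
  usage_pct <- 100 * usage / max(sum(usage), 1L)
  structure(list(archive = front, history = history,
                 n_generations = max(history$generation),
                 n_evaluations = n_distinct,
                 terminated_early = terminated_early,
                 classifier_usage = usage_pct,
                 variant = variant, config = config),
            class = "nsga_result")
}

# NSGA-II survivor truncation: whole fronts, then crowding on the splitter.
nsga2_truncate <- function(objs, N) {
  fronts <- nds_min(objs)
  surv <- integer(0)
  for (f in fronts) {
    if (length(surv) + length(f) <= N) {
      surv <- c(surv, f)
      if (length(surv) == N) break
    } else {
      cd <- crowding_distance(objs[f, , drop = FALSE])
      need <- N - length(surv)
      surv <- c(surv, f[order(-cd)][seq_len(need)])
      break
    }
  }
  surv
}

#' @export
print.nsga_result <- function(x, ...) {
  cat(sprintf(
    "<nsga_result NSGA-%s> %d generations, %d distinct evaluations%s\n",
    x$variant, x$n_generations, x$n_evaluations,
    if (x$terminated_early) " (tolerance met)" else ""))
  print(x$archive[, c("no", "acc", "classifier")])
  invisible(x)
}
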