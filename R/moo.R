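# Multi-objective channel selection: maximize cross-validated accuracy
# (CA), minimize the number of selected channels (no_ch), with one extra
# integer gene tuning the classifier. Solutions are encoded as a binary
# channel vector of length C plus the parameter gene — C+1 genes per
# chromosome / dimensions per particle. NSGA-II, NSGA-III and MOPSO are
# implemented from primitives (non-dominated sorting, crowding distance,
# reference-point niching, external archive).

#' Settings of the multi-objective optimisers
#'
#' @param population_size Even number >= 4 (default 100).
#' @param max_iter Number of generations / swarm iterations (default 50).
#' @param crossover_prob Per-pair probability of uniform crossover
#'   (NSGA; default 0.9).
#' @param mutation_prob Per-gene bit-flip / redraw probability; default
#'   `1 / (C + 1)` at run time.
#' @param seed Seed controlling the full run.
#' @param nsga3_divisions Das-Dennis divisions for NSGA-III reference
#'   points; default `population_size - 1` so the point count matches
#'   the population.
#' @param archive_size MOPSO external archive capacity (default 100).
#' @param inertia,cognitive,social MOPSO velocity coefficients
#'   (defaults 0.5, 1.8, 1.8).
#' @param turbulence_prob MOPSO per-particle mutation probability;
#'   default `1 / (C + 1)`.
#' @return An object of class `moo_config`.
#' @export
moo_config <- function(population_size = 100L, max_iter = 50L,
                       crossover_prob = 0.9, mutation_prob = NULL,
                       seed = 1L, nsga3_divisions = NULL,
                       archive_size = 100L, inertia = 0.5,
                       cognitive = 1.8, social = 1.8,
                       turbulence_prob = NULL) {
  population_size <- as.integer(population_size)
  if (population_size < 4L || population_size %% 2L != 0L) {
    stop("`population_size` must be an even number >= 4", call. = FALSE)
  }
  stopifnot(max_iter >= 1L, crossover_prob >= 0, crossover_prob <= 1)
  structure(list(population_size = population_size,
                 max_iter = as.integer(max_iter),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob, seed = as.integer(seed),
                 nsga3_divisions = nsga3_divisions,
                 archive_size = as.integer(archive_size), inertia = inertia,
                 cognitive = cognitive, social = social,
                 turbulence_prob = turbulence_prob),
            class = "moo_config")
}

#' Construct a candidate solution
#'
#' @param genes Binary (0/1) channel-inclusion vector; at least one 1.
#' @param param Integer classifier-parameter gene.
#' @return An object of class `moo_solution` with `genes`, `param`,
#'   `accuracy` (NA until evaluated) and `no_ch`.
#' @export
moo_solution <- function(genes, param) {
  genes <- as.integer(genes)
  if (!all(genes %in% c(0L, 1L))) stop("`genes` must be 0/1", call. = FALSE)
  if (sum(genes) < 1L) stop("at least one channel must be selected (no_ch >= 1)",
                            call. = FALSE)
  structure(list(genes = genes, param = as.integer(param),
                 accuracy = NA_real_, no_ch = sum(genes)),
            class = "moo_solution")
}

#' Evaluate a solution's objectives
#'
#' Computes CA by 10-fold cross-validation restricted to the selected
#' channels with the classifier parameter taken from the param gene, and
#' no_ch as the popcount of the channel genes. Results are cached by
#' genotype so revisited solutions cost nothing.
#'
#' @param sol A [moo_solution()].
#' @param fm A `feature_matrix`.
#' @param family Classifier family, see [classifier_spec()].
#' @param cv A [cv_config()]; its seed is shared across all evaluations
#'   of one optimisation run (paired comparisons).
#' @param cache Optional environment used as genotype cache.
#' @return The solution with `accuracy` filled in.
#' @export
evaluate_solution <- function(sol, fm, family = "knn", cv = cv_config(),
                              cache = NULL) {
  stopifnot(inherits(sol, "moo_solution"))
  key <- paste0(paste(sol$genes, collapse = ""), "|", sol$param)
  if (!is.null(cache) && !is.null(cache[[key]])) {
    sol$accuracy <- cache[[key]]
    return(sol)
  }
  spec <- classifier_spec(family, sol$param)
  mask <- channel_columns(fm, as.logical(sol$genes))
  sol$accuracy <- crossval_evaluate(fm, mask, spec, cv)$accuracy
  if (!is.null(cache)) cache[[key]] <- sol$accuracy
  sol
}

# a dominates b (maximize ca, minimize no_ch)
dominates <- function(ca_a, no_a, ca_b, no_b) {
  ca_a >= ca_b && no_a <= no_b && (ca_a > ca_b || no_a < no_b)
}

#' Fast non-dominated sorting
#'
#' Sorts points of the (CA, no_ch) objective space into fronts: front 1
#' holds the mutually non-dominated points, front 2 those dominated only
#' by front 1, and so on. Dominance: a dominates b when `CA_a >= CA_b`
#' and `no_ch_a <= no_ch_b`, at least one strictly.
#'
#' @param objs Two-column matrix (or data.frame): CA then no_ch.
#' @return List of integer index vectors, one per front.
#' @export
#' @examples
#' fast_nondominated_sort(rbind(c(90, 5), c(95, 5), c(95, 9)))
fast_nondominated_sort <- function(objs) {
  objs <- as.matrix(objs)
  n <- nrow(objs)
  if (n == 0L) return(list())
  ca <- objs[, 1L]; no <- objs[, 2L]
  dominated_by <- integer(n)           # count of dominators
  dominates_set <- vector("list", n)
  for (i in seq_len(n)) {
    # vectorized pairwise dominance of i over all j
    d_i_over <- ca[i] >= ca & no[i] <= no & (ca[i] > ca | no[i] < no)
    dominates_set[[i]] <- which(d_i_over)
    dominated_by <- dominated_by + as.integer(d_i_over)
  }
  fronts <- list()
  current <- which(dominated_by == 0L)
  remaining <- dominated_by
  while (length(current) > 0L) {
    fronts[[length(fronts) + 1L]] <- current
    remaining[current] <- -1L
    for (i in current) remaining[dominates_set[[i]]] <-
        remaining[dominates_set[[i]]] - 1L
    current <- which(remaining == 0L)
  }
  fronts
}

#' Crowding distance of a front
#'
#' NSGA-II's objective-space density estimate: for each objective the
#' front is sorted, boundary points get infinite distance and interior
#' points the normalized gap between their neighbours; per-point
#' distances sum over objectives. A zero objective range contributes 0.
#'
#' @param objs Two-column matrix of a single front's objectives.
#' @return Numeric vector of distances.
#' @export
crowding_distance <- function(objs) {
  objs <- as.matrix(objs)
  n <- nrow(objs)
  if (n == 0L) return(numeric(0))
  d <- numeric(n)
  for (j in seq_len(ncol(objs))) {
    ord <- order(objs[, j])
    rng <- objs[ord[n], j] - objs[ord[1L], j]
    d[ord[c(1L, n)]] <- Inf
    if (n > 2L && rng > 0) {
      gaps <- (objs[ord[3:n], j] - objs[ord[1:(n - 2L)], j]) / rng
      d[ord[2:(n - 1L)]] <- d[ord[2:(n - 1L)]] + gaps
    }
  }
  d
}

#' Das-Dennis reference points on the unit simplex
#'
#' @param n_obj Number of objectives (default 2).
#' @param divisions Number of divisions per objective axis.
#' @return Matrix with `n_obj` columns; each row sums to 1.
#' @export
#' @examples
#' reference_points(2, 4)
reference_points <- function(n_obj = 2L, divisions = 4L) {
  stopifnot(n_obj >= 2L, divisions >= 1L)
  compose <- function(left, dims) {
    if (dims == 1L) return(matrix(left, ncol = 1L))
    do.call(rbind, lapply(0:left, function(i) {
      cbind(i, compose(left - i, dims - 1L))
    }))
  }
  pts <- compose(as.integer(divisions), as.integer(n_obj)) / divisions
  dimnames(pts) <- NULL
  pts
}

# ---- shared GA machinery ------------------------------------------------

random_solution <- function(C, prange) {
  genes <- as.integer(runif(C) < 0.5)
  if (sum(genes) == 0L) genes[sample.int(C, 1L)] <- 1L
  list(genes = genes, param = sample(prange[1L]:prange[2L], 1L),
       ca = NA_real_, no_ch = sum(genes))
}

repair_genes <- function(genes) {
  if (sum(genes) == 0L) genes[sample.int(length(genes), 1L)] <- 1L
  genes
}

vary_pair <- function(p1, p2, C, prange, cx_prob, mut_prob) {
  g1 <- p1$genes; g2 <- p2$genes
  q1 <- p1$param; q2 <- p2$param
  if (runif(1) < cx_prob) {              # uniform crossover, per-gene 0.5
    swap <- runif(C) < 0.5
    tmp <- g1[swap]; g1[swap] <- g2[swap]; g2[swap] <- tmp
    if (runif(1) < 0.5) { tmp <- q1; q1 <- q2; q2 <- tmp }
  }
  mutate <- function(g, q) {
    flip <- runif(C) < mut_prob
    g[flip] <- 1L - g[flip]
    if (runif(1) < mut_prob) q <- sample(prange[1L]:prange[2L], 1L)
    list(genes = repair_genes(g), param = q, ca = NA_real_, no_ch = NA_integer_)
  }
  list(mutate(g1, q1), mutate(g2, q2))
}

evaluate_pop <- function(pop, objective) {
  for (i in seq_along(pop)) {
    if (is.na(pop[[i]]$ca)) {
      pop[[i]]$ca <- objective(pop[[i]]$genes, pop[[i]]$param)
      pop[[i]]$no_ch <- sum(pop[[i]]$genes)
    }
  }
  pop
}

pop_objs <- function(pop) {
  cbind(ca = vapply(pop, `[[`, 0, "ca"),
        no_ch = vapply(pop, function(s) sum(s$genes), 0L))
}

# external archive: mutually non-dominated solutions with genotype dedup
update_archive <- function(archive, pop, cap = Inf) {
  all_sols <- c(archive, pop)
  keys <- vapply(all_sols, function(s)
    paste0(paste(s$genes, collapse = ""), "|", s$param), "")
  all_sols <- all_sols[!duplicated(keys)]
  objs <- pop_objs(all_sols)
  fr <- fast_nondominated_sort(objs)
  arch <- all_sols[fr[[1L]]]
  while (length(arch) > cap) {
    cd <- crowding_distance(pop_objs(arch))
    arch <- arch[-which.min(cd)]
  }
  arch
}

archive_summary <- function(archive) {
  objs <- pop_objs(archive)
  data.frame(no_ch = objs[, 2L], accuracy = objs[, 1L])[order(objs[, 2L]), ,
                                                        drop = FALSE]
}

# objective with genotype cache and call counter; used by all optimisers
make_moo_objective <- function(fm, family, cv) {
  cache <- new.env(parent = emptyenv())
  n_calls <- 0L
  f <- function(genes, param) {
    key <- paste0(paste(genes, collapse = ""), "|", param)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    n_calls <<- n_calls + 1L
    spec <- classifier_spec(family, param)
    ca <- crossval_evaluate(fm, channel_columns(fm, as.logical(genes)),
                            spec, cv)$accuracy
    cache[[key]] <- ca
    ca
  }
  attr(f, "count") <- function() n_calls
  f
}

binary_tournament <- function(rank, crowd) {
  n <- length(rank)
  pick <- function() {
    i <- sample.int(n, 2L)
    if (rank[i[1L]] < rank[i[2L]]) return(i[1L])
    if (rank[i[2L]] < rank[i[1L]]) return(i[2L])
    if (crowd[i[1L]] >= crowd[i[2L]]) i[1L] else i[2L]
  }
  pick()
}

rank_of <- function(fronts, n) {
  r <- integer(n)
  for (k in seq_along(fronts)) r[fronts[[k]]] <- k
  r
}

finalize_front <- function(archive, history, evaluations, algorithm,
                           channel_labels) {
  ord <- order(vapply(archive, function(s) sum(s$genes), 0L),
               -vapply(archive, `[[`, 0, "ca"))
  structure(list(solutions = archive[ord], history = history,
                 evaluations = evaluations, algorithm = algorithm,
                 channel_labels = channel_labels),
            class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("<pareto_front> %s: %d non-dominated solutions (%d evaluations)\n",
              x$algorithm, length(x$solutions), x$evaluations))
  print(as.data.frame(x))
  invisible(x)
}

#' Summarise a Pareto front as a data frame
#' @param x A `pareto_front`.
#' @param ... Unused.
#' @return data.frame with `no_ch`, `accuracy`, `param`, `channels`.
#' @export
as.data.frame.pareto_front <- function(x, ...) {
  data.frame(
    no_ch = vapply(x$solutions, function(s) sum(s$genes), 0L),
    accuracy = vapply(x$solutions, `[[`, 0, "ca"),
    param = vapply(x$solutions, `[[`, 0L, "param"),
    channels = vapply(x$solutions, function(s) {
      if (is.null(x$channel_labels)) paste(which(s$genes == 1L), collapse = ",")
      else paste(x$channel_labels[s$genes == 1L], collapse = ",")
    }, ""),
    stringsAsFactors = FALSE)
}

# shared front-end: resolve objective, channel count and param range
resolve_problem <- function(fm, family, cv, objective, n_channels, prange) {
  if (is.null(objective)) {
    stopifnot(inherits(fm, "feature_matrix"))
    objective <- make_moo_objective(fm, family, cv)
    n_channels <- length(fm$channel_labels)
    prange <- param_range(family)
    labels <- fm$channel_labels
  } else {
    if (is.null(n_channels)) stop("`n_channels` required with a custom objective",
                                  call. = FALSE)
    if (is.null(prange)) prange <- c(1L, 1L)
    labels <- if (!is.null(fm)) fm$channel_labels else NULL
  }
  list(objective = objective, C = as.integer(n_channels),
       prange = as.integer(prange), labels = labels)
}

#' NSGA-II channel selection
#'
#' Elitist generational loop: binary-tournament parent selection by
#' (non-domination rank, crowding distance), uniform crossover on the
#' channel genes, bit-flip mutation plus integer redraw of the parameter
#' gene, repair to at least one channel, and (mu + lambda) survival by
#' rank then crowding. An external archive accumulates every
#' non-dominated solution encountered and is returned as the front.
#'
#' @param fm A `feature_matrix` (may be `NULL` with a custom
#'   `objective`).
#' @param family Classifier family for the parameter gene.
#' @param cfg A [moo_config()].
#' @param cv A [cv_config()] shared by all evaluations.
#' @param objective Optional custom objective
#'   `function(genes, param) -> CA` (for algorithmic studies and tests);
#'   requires `n_channels`.
#' @param n_channels,prange Problem dimensions when `objective` is
#'   custom: channel count and inclusive parameter range.
#' @return A `pareto_front`: `solutions` (list of gene/param/ca),
#'   `history` (per-generation archive summaries), `evaluations`
#'   (distinct genotypes evaluated).
#' @export
nsga2_run <- function(fm = NULL, family = "knn", cfg = moo_config(),
                      cv = cv_config(), objective = NULL,
                      n_channels = NULL, prange = NULL) {
  prob <- resolve_problem(fm, family, cv, objective, n_channels, prange)
  with_private_seed(cfg$seed, {
    C <- prob$C
    mut_prob <- cfg$mutation_prob %||% (1 / (C + 1))
    pop <- replicate(cfg$population_size, random_solution(C, prob$prange),
                     simplify = FALSE)
    pop <- evaluate_pop(pop, prob$objective)
    archive <- update_archive(list(), pop)
    history <- list(archive_summary(archive))
    for (gen in seq_len(cfg$max_iter)) {
      objs <- pop_objs(pop)
      fronts <- fast_nondominated_sort(objs)
      rank <- rank_of(fronts, nrow(objs))
      crowd <- numeric(nrow(objs))
      for (fr in fronts) crowd[fr] <- crowding_distance(objs[fr, , drop = FALSE])
      offspring <- vector("list", cfg$population_size)
      i <- 1L
      while (i < cfg$population_size) {
        p1 <- pop[[binary_tournament(rank, crowd)]]
        p2 <- pop[[binary_tournament(rank, crowd)]]
        kids <- vary_pair(p1, p2, C, prob$prange, cfg$crossover_prob, mut_prob)
        offspring[[i]] <- kids[[1L]]; offspring[[i + 1L]] <- kids[[2L]]
        i <- i + 2L
      }
      offspring <- evaluate_pop(offspring, prob$objective)
      pop <- survival_nsga2(c(pop, offspring), cfg$population_size)
      archive <- update_archive(archive, pop)
      history[[gen + 1L]] <- archive_summary(archive)
    }
    finalize_front(archive, history, evaluator_count(prob$objective),
                   "nsga2", prob$labels)
  })
}

survival_nsga2 <- function(pop, mu) {
  objs <- pop_objs(pop)
  fronts <- fast_nondominated_sort(objs)
  chosen <- integer(0)
  for (fr in fronts) {
    if (length(chosen) + length(fr) <= mu) {
      chosen <- c(chosen, fr)
    } else {
      cd <- crowding_distance(objs[fr, , drop = FALSE])
      need <- mu - length(chosen)
      chosen <- c(chosen, fr[order(-cd)[seq_len(need)]])
      break
    }
  }
  pop[chosen]
}

#' NSGA-III channel selection
#'
#' Same generational loop as [nsga2_run()] but survival of the last
#' admitted front uses reference-point niching: objectives are min-max
#' normalized (CA negated so both objectives are minimized), members are
#' associated with the Das-Dennis reference ray of smallest
#' perpendicular distance, and underrepresented rays are filled first.
#'
#' @inheritParams nsga2_run
#' @return A `pareto_front`.
#' @export
nsga3_run <- function(fm = NULL, family = "knn", cfg = moo_config(),
                      cv = cv_config(), objective = NULL,
                      n_channels = NULL, prange = NULL) {
  prob <- resolve_problem(fm, family, cv, objective, n_channels, prange)
  divisions <- cfg$nsga3_divisions %||% (cfg$population_size - 1L)
  refs <- reference_points(2L, divisions)
  with_private_seed(cfg$seed, {
    C <- prob$C
    mut_prob <- cfg$mutation_prob %||% (1 / (C + 1))
    pop <- replicate(cfg$population_size, random_solution(C, prob$prange),
                     simplify = FALSE)
    pop <- evaluate_pop(pop, prob$objective)
    archive <- update_archive(list(), pop)
    history <- list(archive_summary(archive))
    for (gen in seq_len(cfg$max_iter)) {
      objs <- pop_objs(pop)
      fronts <- fast_nondominated_sort(objs)
      rank <- rank_of(fronts, nrow(objs))
      crowd <- numeric(nrow(objs))
      for (fr in fronts) crowd[fr] <- crowding_distance(objs[fr, , drop = FALSE])
      offspring <- vector("list", cfg$population_size)
      i <- 1L
      while (i < cfg$population_size) {
        p1 <- pop[[binary_tournament(rank, crowd)]]
        p2 <- pop[[binary_tournament(rank, crowd)]]
        kids <- vary_pair(p1, p2, C, prob$prange, cfg$crossover_prob, mut_prob)
        offspring[[i]] <- kids[[1L]]; offspring[[i + 1L]] <- kids[[2L]]
        i <- i + 2L
      }
      offspring <- evaluate_pop(offspring, prob$objective)
      pop <- survival_nsga3(c(pop, offspring), cfg$population_size, refs)
      archive <- update_archive(archive, pop)
      history[[gen + 1L]] <- archive_summary(archive)
    }
    finalize_front(archive, history, evaluator_count(prob$objective),
                   "nsga3", prob$labels)
  })
}

survival_nsga3 <- function(pop, mu, refs) {
  objs <- pop_objs(pop)
  fronts <- fast_nondominated_sort(objs)
  chosen <- integer(0)
  last <- integer(0)
  for (fr in fronts) {
    if (length(chosen) + length(fr) <= mu) {
      chosen <- c(chosen, fr)
      if (length(chosen) == mu) return(pop[chosen])
    } else { last <- fr; break }
  }
  under_sel <- c(chosen, last)
  # minimization form: f1 = -CA, f2 = no_ch; min-max normalize over the
  # members under consideration
  f <- cbind(-objs[under_sel, 1L], objs[under_sel, 2L])
  lo <- apply(f, 2L, min); hi <- apply(f, 2L, max)
  rng <- pmax(hi - lo, 1e-12)
  fn <- sweep(sweep(f, 2L, lo), 2L, rng, "/")
  # perpendicular distance of each member to each reference ray
  assoc <- integer(nrow(fn)); dist_r <- numeric(nrow(fn))
  for (i in seq_len(nrow(fn))) {
    w <- fn[i, ]
    dists <- vapply(seq_len(nrow(refs)), function(r) {
      u <- refs[r, ]; un <- u / sqrt(sum(u^2))
      proj <- sum(w * un)
      sqrt(max(sum(w^2) - proj^2, 0))
    }, 0)
    assoc[i] <- which.min(dists)
    dist_r[i] <- min(dists)
  }
  member_of <- function(global_idx) match(global_idx, under_sel)
  niche_count <- tabulate(assoc[member_of(chosen)], nbins = nrow(refs))
  pool <- last
  while (length(chosen) < mu && length(pool) > 0L) {
    pool_assoc <- assoc[member_of(pool)]
    active <- sort(unique(pool_assoc))
    jmin <- active[which.min(niche_count[active])]
    cand <- pool[pool_assoc == jmin]
    pick <- if (niche_count[jmin] == 0L) {
      cand[which.min(dist_r[member_of(cand)])]
    } else {
      cand[sample.int(length(cand), 1L)]
    }
    chosen <- c(chosen, pick)
    pool <- setdiff(pool, pick)
    niche_count[jmin] <- niche_count[jmin] + 1L
  }
  pop[chosen]
}

#' Multi-objective particle swarm channel selection
#'
#' Particles hold relaxed positions in `[0,1]^C` for the channel genes
#' (thresholded at 0.5 to obtain the binary mask) plus one continuous
#' dimension for the parameter gene (rounded and clipped). Velocities
#' follow the canonical inertia + cognitive + social update with leaders
#' drawn from the external non-dominated archive, favouring sparsely
#' crowded archive members; a personal best is replaced when dominated
#' (ties resolved at random). A low-rate turbulence redraw keeps the
#' swarm exploring. The archive is truncated to `archive_size` by
#' removing its most crowded member.
#'
#' @inheritParams nsga2_run
#' @return A `pareto_front`.
#' @export
mopso_run <- function(fm = NULL, family = "knn", cfg = moo_config(),
                      cv = cv_config(), objective = NULL,
                      n_channels = NULL, prange = NULL) {
  prob <- resolve_problem(fm, family, cv, objective, n_channels, prange)
  with_private_seed(cfg$seed, {
    C <- prob$C
    D <- C + 1L
    n <- cfg$population_size
    turb <- cfg$turbulence_prob %||% (1 / (C + 1))
    plo <- prob$prange[1L]; phi <- prob$prange[2L]
    pos <- matrix(runif(n * D), n, D)
    pos[, D] <- plo + pos[, D] * (phi - plo)
    vel <- matrix(0, n, D)
    vmax <- c(rep(0.25, C), 0.25 * max(phi - plo, 1))

    decode <- function(p) {
      genes <- as.integer(p[seq_len(C)] >= 0.5)
      if (sum(genes) == 0L) {            # repair: activate the largest position
        genes[which.max(p[seq_len(C)])] <- 1L
      }
      list(genes = genes, param = as.integer(pmin(pmax(round(p[D]), plo), phi)))
    }
    eval_at <- function(p) {
      dec <- decode(p)
      list(genes = dec$genes, param = dec$param,
           ca = prob$objective(dec$genes, dec$param), no_ch = sum(dec$genes))
    }

    swarm <- lapply(seq_len(n), function(i) eval_at(pos[i, ]))
    pbest <- swarm
    archive <- update_archive(list(), swarm, cfg$archive_size)
    history <- list(archive_summary(archive))

    pick_leader <- function() {
      m <- length(archive)
      if (m == 1L) return(archive[[1L]])
      cd <- crowding_distance(pop_objs(archive))
      cd[!is.finite(cd)] <- max(cd[is.finite(cd)], 1) * 2 + 1
      i <- sample.int(m, 2L)
      archive[[if (cd[i[1L]] >= cd[i[2L]]) i[1L] else i[2L]]]
    }

    for (iter in seq_len(cfg$max_iter)) {
      for (i in seq_len(n)) {
        leader <- pick_leader()
        lp <- c(leader$genes, leader$param)
        bp <- c(pbest[[i]]$genes, pbest[[i]]$param)
        r1 <- runif(D); r2 <- runif(D)
        vel[i, ] <- cfg$inertia * vel[i, ] +
          cfg$cognitive * r1 * (bp - pos[i, ]) +
          cfg$social * r2 * (lp - pos[i, ])
        vel[i, ] <- pmin(pmax(vel[i, ], -vmax), vmax)
        pos[i, ] <- pos[i, ] + vel[i, ]
        pos[i, seq_len(C)] <- pmin(pmax(pos[i, seq_len(C)], 0), 1)
        pos[i, D] <- pmin(pmax(pos[i, D], plo), phi)
        # turbulence: low-rate per-dimension redraw keeps the swarm from
        # collapsing onto early leaders
        redraw <- runif(D) < turb
        if (any(redraw)) {
          ch_r <- which(redraw[seq_len(C)])
          pos[i, ch_r] <- runif(length(ch_r))
          if (redraw[D]) pos[i, D] <- plo + runif(1) * (phi - plo)
        }
        swarm[[i]] <- eval_at(pos[i, ])
        new <- swarm[[i]]; old <- pbest[[i]]
        if (dominates(new$ca, new$no_ch, old$ca, old$no_ch) ||
            (!dominates(old$ca, old$no_ch, new$ca, new$no_ch) &&
             runif(1) < 0.5)) {
          pbest[[i]] <- new
        }
      }
      archive <- update_archive(archive, swarm, cfg$archive_size)
      history[[iter + 1L]] <- archive_summary(archive)
    }
    finalize_front(archive, history, evaluator_count(prob$objective),
                   "mopso", prob$labels)
  })
}
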