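# Random sequential attachment of interior trimers to the core lattice:
# exact jamming distribution, Monte Carlo simulation, and a co-assembly
# variant in which binding happens while the core itself grows.

#' Exact jamming distribution of sequential attachment
#'
#' Computes the exact absorbing-state distribution of the naive assembly
#' model: trimers attach one at a time to a preformed core, each step picking
#' uniformly at random among the vertices whose addition keeps the occupancy
#' valid under the exclusion rule, until no such vertex remains (the
#' configuration is jammed).  Probabilities are obtained by recursion over
#' occupancy states, memoized on canonical forms (the chain's law is
#' invariant under the rotation group, so all states of an orbit share one
#' terminal-class distribution).
#'
#' On the dodecahedral lattice with the volume-occluding rule
#' (`min_distance = 3`) the chain jams at size 2 (the antipodal pair, class
#' 2S) with probability 1/10, at size 3 (class 3S) with probability 3/5, and
#' saturates at size 4 with probability 3/10 -- 3/20 = 15% for each of the
#' two tetrahedral arrangements.
#'
#' @param core a [`build_core()`] lattice.
#' @param rule an [`exclusion_rule()`] with `min_distance >= 2`.
#' @param group optional precomputed [`rotation_group()`].
#' @return a `JammingDistribution`: list with `table` (data frame of
#'   terminal classes: `alias`, `canonical_key`, `size`, `point_group`,
#'   `probability`), `provenance = "exact"`, `core`, `min_distance`, and
#'   `n_states_visited` (distinct canonical states expanded).
#' @examples
#' jd <- exact_jamming_distribution(build_core("icosahedral-60mer"),
#'                                  exclusion_rule(3))
#' subset(jd$table, size == 4)$probability  # 0.15 0.15
#' @export
exact_jamming_distribution <- function(core, rule, group = NULL) {
  stopifnot(inherits(core, "CoreLattice"), inherits(rule, "ExclusionRule"))
  if (rule$min_distance < 2L) stop("min_distance must be >= 2")
  if (is.null(group)) group <- rotation_group(core)
  md <- rule$min_distance

  memo <- new.env(parent = emptyenv())
  rec <- function(occ) {
    key <- occ_key(canonical_form(occ, group))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    add <- addable_vertices(occ, md, core)
    if (length(add) == 0L) {
      res <- stats::setNames(1, key)
    } else {
      res <- numeric(0)
      w <- 1 / length(add)
      for (v in add) {
        child <- rec(sort(c(occ, v)))
        for (k in names(child)) {
          res[k] <- (if (k %in% names(res)) res[k] else 0) + w * child[k]
        }
      }
    }
    memo[[key]] <- res
    res
  }
  probs <- rec(integer(0))

  cls <- configuration_classes(core, rule, group = group)
  tab <- cls[cls$jammed, c("alias", "canonical_key", "size", "point_group"),
             drop = FALSE]
  tab$probability <- unname(probs[tab$canonical_key])
  tab$probability[is.na(tab$probability)] <- 0
  rownames(tab) <- NULL
  stopifnot(abs(sum(tab$probability) - 1) < 1e-12)
  structure(
    list(table = tab, provenance = "exact", core = core$name,
         min_distance = md, n_runs = NA_integer_, seed = NA_integer_,
         n_states_visited = length(ls(memo))),
    class = "JammingDistribution")
}

#' @export
print.JammingDistribution <- function(x, ...) {
  cat(sprintf("JammingDistribution (%s) on \"%s\", min_distance = %d\n",
              x$provenance, x$core, x$min_distance))
  if (!is.na(x$n_runs)) cat(sprintf("  runs: %d, seed: %d\n", x$n_runs, x$seed))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Monte Carlo random sequential attachment
#'
#' Simulates the same uniform-over-addable-sites chain as
#' [`exact_jamming_distribution()`] and reports the empirical terminal-class
#' frequencies.  All randomness comes from a single generator seeded once per
#' call with `seed`, runs drawn sequentially, so identical `seed` and
#' `n_runs` give identical output.
#'
#' @inheritParams exact_jamming_distribution
#' @param n_runs number of independent assembly runs (>= 1).
#' @param seed integer seed.
#' @param trajectories if `TRUE`, attach the per-run attachment orders as
#'   attribute `"trajectories"` (list of integer vectors in attachment
#'   order).
#' @return a `JammingDistribution` with `provenance = "monte_carlo"`.
#' @export
simulate_rsa <- function(core, rule, n_runs, seed, group = NULL,
                         trajectories = FALSE) {
  stopifnot(inherits(core, "CoreLattice"), inherits(rule, "ExclusionRule"))
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1L) stop("n_runs must be >= 1")
  if (rule$min_distance < 2L) stop("min_distance must be >= 2")
  if (is.null(group)) group <- rotation_group(core)
  md <- rule$min_distance
  n <- core$n_vertices
  # occupying v blocks every vertex within graph distance md - 1 (incl. v)
  balls <- lapply(seq_len(n), function(v) which(core$dist[v, ] < md))

  set.seed(as.integer(seed))
  canon_cache <- new.env(parent = emptyenv())
  counts <- new.env(parent = emptyenv())
  trajs <- if (trajectories) vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    blocked <- logical(n)
    occ <- integer(0)
    repeat {
      free <- which(!blocked)
      if (length(free) == 0L) break
      v <- free[sample.int(length(free), 1L)]
      occ <- c(occ, v)
      blocked[balls[[v]]] <- TRUE
    }
    if (trajectories) trajs[[r]] <- occ
    rkey <- occ_key(occ)
    ckey <- canon_cache[[rkey]]
    if (is.null(ckey)) {
      ckey <- occ_key(canonical_form(occ, group))
      canon_cache[[rkey]] <- ckey
    }
    counts[[ckey]] <- (if (is.null(counts[[ckey]])) 0L else counts[[ckey]]) + 1L
  }

  cls <- configuration_classes(core, rule, group = group)
  tab <- cls[cls$jammed, c("alias", "canonical_key", "size", "point_group"),
             drop = FALSE]
  tab$probability <- vapply(tab$canonical_key, function(k) {
    cnt <- counts[[k]]
    if (is.null(cnt)) 0 else cnt / n_runs
  }, numeric(1))
  rownames(tab) <- NULL
  out <- structure(
    list(table = tab, provenance = "monte_carlo", core = core$name,
         min_distance = md, n_runs = n_runs, seed = as.integer(seed),
         n_states_visited = NA_integer_),
    class = "JammingDistribution")
  if (trajectories) attr(out, "trajectories") <- trajs
  out
}

#' Monte Carlo co-assembly of core and interior trimers
#'
#' Variant of the assembly model in which the interior protein binds while
#' the core itself is being built, rather than only after completion.  Core
#' vertices are added in a uniformly random order.  A vertex becomes
#' *competent* for interior binding at the moment it and its three
#' neighbours are all present (its bridge pockets then exist); at that
#' moment, if it is not excluded by the trimers already bound, it binds one
#' with probability `p_bind`.  Once the core is complete, any remaining
#' non-excluded vertices fill sequentially exactly as in [`simulate_rsa()`],
#' so `p_bind = 0` reduces to the preformed-core model.  Attachment is
#' irreversible throughout.
#'
#' Early commitment to sites on a partial core steers the process away from
#' the jammed suboptimal traps, so increasing `p_bind` enriches saturated
#' (maximal) terminal arrangements relative to the preformed-core chain.
#'
#' @inheritParams simulate_rsa
#' @param p_bind probability in `[0, 1]` that a newly competent,
#'   non-excluded vertex binds a trimer at the moment of competence.
#' @return a `JammingDistribution` with `provenance = "co_assembly"`.
#' @export
simulate_coassembly <- function(core, rule, p_bind, n_runs, seed,
                                group = NULL) {
  stopifnot(inherits(core, "CoreLattice"), inherits(rule, "ExclusionRule"))
  if (!is.numeric(p_bind) || length(p_bind) != 1L || is.na(p_bind) ||
      p_bind < 0 || p_bind > 1) {
    stop("p_bind must be a probability in [0, 1]")
  }
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1L) stop("n_runs must be >= 1")
  if (rule$min_distance < 2L) stop("min_distance must be >= 2")
  if (is.null(group)) group <- rotation_group(core)
  md <- rule$min_distance
  n <- core$n_vertices
  nbrs <- neighbour_list(core)
  balls <- lapply(seq_len(n), function(v) which(core$dist[v, ] < md))

  set.seed(as.integer(seed))
  canon_cache <- new.env(parent = emptyenv())
  counts <- new.env(parent = emptyenv())
  for (r in seq_len(n_runs)) {
    ord <- sample.int(n)
    present <- logical(n)
    evaluated <- logical(n)
    blocked <- logical(n)
    occ <- integer(0)
    for (u in ord) {
      present[u] <- TRUE
      cand <- c(u, nbrs[[u]])
      newly <- cand[present[cand] & !evaluated[cand] &
                      vapply(cand, function(v) all(present[nbrs[[v]]]),
                             logical(1))]
      if (length(newly) > 1L) newly <- newly[sample.int(length(newly))]
      for (v in newly) {
        evaluated[v] <- TRUE
        if (!blocked[v] && stats::runif(1) < p_bind) {
          occ <- c(occ, v)
          blocked[balls[[v]]] <- TRUE
        }
      }
    }
    repeat {
      free <- which(!blocked)
      if (length(free) == 0L) break
      v <- free[sample.int(length(free), 1L)]
      occ <- c(occ, v)
      blocked[balls[[v]]] <- TRUE
    }
    rkey <- occ_key(occ)
    ckey <- canon_cache[[rkey]]
    if (is.null(ckey)) {
      ckey <- occ_key(canonical_form(occ, group))
      canon_cache[[rkey]] <- ckey
    }
    counts[[ckey]] <- (if (is.null(counts[[ckey]])) 0L else counts[[ckey]]) + 1L
  }

  cls <- configuration_classes(core, rule, group = group)
  tab <- cls[cls$jammed, c("alias", "canonical_key", "size", "point_group"),
             drop = FALSE]
  tab$probability <- vapply(tab$canonical_key, function(k) {
    cnt <- counts[[k]]
    if (is.null(cnt)) 0 else cnt / n_runs
  }, numeric(1))
  rownames(tab) <- NULL
  structure(
    list(table = tab, provenance = "co_assembly", core = core$name,
         min_distance = md, n_runs = n_runs, seed = as.integer(seed),
         p_bind = p_bind, n_states_visited = NA_integer_),
    class = "JammingDistribution")
}

#' Saturation fraction of a jamming distribution
#'
#' Probability mass on terminal classes of the maximum size present in the
#' distribution's class table -- the fraction of particles whose interior is
#' complete.
#'
#' @param jd a `JammingDistribution`.
#' @return numeric in `[0, 1]`.
#' @export
saturation_fraction <- function(jd) {
  stopifnot(inherits(jd, "JammingDistribution"))
  smax <- max(jd$table$size)
  sum(jd$table$probability[jd$table$size == smax])
}
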