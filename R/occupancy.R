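# Occupancy patterns of interior trimers on a core lattice, the
# steric-exclusion rule, and canonical classification under rotation.

#' Steric-exclusion rule for interior trimers
#'
#' The rule states the minimum graph distance allowed between any two
#' occupied trimer sites:
#' \describe{
#'   \item{`min_distance = 3`}{volume-occluding trimers: two occupied sites
#'     must have at least two intermediate trimers between them.  This is the
#'     restriction imposed by the bulky interior basket of the trimeric PX
#'     core-binding domain.}
#'   \item{`min_distance = 2`}{non-occluding trimers: simple non-adjacency
#'     (each bound trimer only consumes the three bridge pockets incident to
#'     its own vertex).}
#'   \item{`min_distance = 1`}{no exclusion.}
#' }
#'
#' @param min_distance integer >= 1.
#' @return an `ExclusionRule` (list with `min_distance`, `description`).
#' @export
exclusion_rule <- function(min_distance) {
  md <- as.integer(min_distance)
  if (is.na(md) || md < 1L) stop("min_distance must be an integer >= 1")
  desc <- switch(as.character(md),
    "1" = "no exclusion",
    "2" = "non-occluding trimers: occupied sites pairwise non-adjacent",
    "3" = paste0("volume-occluding trimers: at least two intermediate ",
                 "trimers between any two occupied sites"),
    sprintf("occupied sites pairwise at graph distance >= %d", md))
  structure(list(min_distance = md, description = desc),
            class = "ExclusionRule")
}

#' @export
print.ExclusionRule <- function(x, ...) {
  cat(sprintf("ExclusionRule: min graph distance %d (%s)\n",
              x$min_distance, x$description))
  invisible(x)
}

#' Is an occupancy valid under the exclusion rule?
#'
#' @param occ integer vector of occupied vertex ids (an occupancy).
#' @param rule an [`exclusion_rule()`].
#' @param core a [`build_core()`] lattice.
#' @return `TRUE` iff every pair of occupied vertices is at graph distance
#'   at least `rule$min_distance`.
#' @export
is_valid <- function(occ, rule, core) {
  stopifnot(inherits(rule, "ExclusionRule"), inherits(core, "CoreLattice"))
  occ <- check_vertex_ids(core, occ)
  if (anyDuplicated(occ)) return(FALSE)
  if (length(occ) < 2L) return(TRUE)
  d <- core$dist[occ, occ]
  all(d[upper.tri(d)] >= rule$min_distance)
}

#' Enumerate all valid occupancies
#'
#' Exhaustive, duplicate-free enumeration of occupancies satisfying the
#' exclusion rule, by depth-first extension in increasing vertex-id order
#' (a candidate is only added if its id exceeds the current maximum, so each
#' set is produced exactly once).
#'
#' @inheritParams is_valid
#' @param size occupancy size to enumerate, or `NULL` for all sizes
#'   (including the empty occupancy).
#' @return list of integer vectors in deterministic (lexicographic) order.
#' @examples
#' core <- build_core("icosahedral-60mer")
#' length(enumerate_valid(core, exclusion_rule(3), size = 4))  # 10
#' @export
enumerate_valid <- function(core, rule, size = NULL) {
  stopifnot(inherits(rule, "ExclusionRule"), inherits(core, "CoreLattice"))
  if (!is.null(size)) {
    size <- as.integer(size)
    if (is.na(size) || size < 0L) stop("size must be a non-negative integer")
  }
  md <- rule$min_distance
  D <- core$dist
  acc <- new.env(parent = emptyenv())
  acc$out <- vector("list", 256L)
  acc$k <- 0L
  push <- function(x) {
    k <- acc$k + 1L
    if (k > length(acc$out)) acc$out <- c(acc$out, vector("list", length(acc$out)))
    acc$out[[k]] <- x
    acc$k <- k
  }
  recurse <- function(cur, cand) {
    if (is.null(size) || length(cur) == size) push(cur)
    if (!is.null(size) && length(cur) >= size) return(invisible(NULL))
    for (v in cand) {
      recurse(c(cur, v), cand[cand > v & D[v, cand] >= md])
    }
    invisible(NULL)
  }
  recurse(integer(0), seq_len(core$n_vertices))
  acc$out[seq_len(acc$k)]
}

# canonical key string for a vertex set (fixed width so string order equals
# lexicographic tuple order)
occ_key <- function(occ) {
  if (length(occ) == 0L) return("(empty)")
  paste(sprintf("%03d", sort(occ)), collapse = "-")
}

#' Canonical form of an occupancy under a rotation group
#'
#' The lexicographically minimal sorted image of the occupied set over all
#' group elements; two occupancies are rotationally equivalent iff their
#' canonical forms are equal.
#'
#' @param occ integer vector of occupied vertex ids.
#' @param group a [`rotation_group()`].
#' @return sorted integer vector, the canonical representative.
#' @export
canonical_form <- function(occ, group) {
  stopifnot(inherits(group, "RotationGroup"))
  if (length(occ) == 0L) return(integer(0))
  best <- NULL
  best_key <- NULL
  for (e in group$elements) {
    img <- sort(e$perm[occ])
    key <- occ_key(img)
    if (is.null(best_key) || key < best_key) {
      best <- img
      best_key <- key
    }
  }
  best
}

#' Is an occupancy jammed (terminally blocked)?
#'
#' A valid occupancy is jammed when no unoccupied vertex can be added without
#' violating the exclusion rule.  Jammed occupancies below the maximum size
#' are the "suboptimal" arrangements (2S, 3S); non-jammed subsets of maximal
#' arrangements are "unsaturated" states (e.g. Y3U).
#'
#' @inheritParams is_valid
#' @return `TRUE` iff no valid single-vertex addition exists.
#' @export
is_jammed <- function(occ, rule, core) {
  occ <- check_vertex_ids(core, occ)
  if (!is_valid(occ, rule, core)) stop("occupancy is not valid under the rule")
  length(addable_vertices(occ, rule$min_distance, core)) == 0L
}

addable_vertices <- function(occ, md, core) {
  if (length(occ) == 0L) return(seq_len(core$n_vertices))
  free <- setdiff(seq_len(core$n_vertices), occ)
  free[vapply(free, function(v) all(core$dist[v, occ] >= md), logical(1))]
}

#' Classify occupancies into rotation classes
#'
#' Partitions a list of labelled occupancies into orbits under the proper
#' rotation group.  Each class records its canonical representative, orbit
#' size, stabilizer order, point-group label of the stabilizer, and (when
#' `rule` is given) whether the class is jammed.
#'
#' @param configs list of integer vectors (occupancies), e.g. from
#'   [`enumerate_valid()`].
#' @param group the lattice's [`rotation_group()`].
#' @param rule optional [`exclusion_rule()`]; needed for the `jammed` flag.
#' @param core the [`build_core()`] lattice the configs live on.
#' @return data frame with one row per class: `canonical_key`, `size`,
#'   `orbit_size`, `stabilizer_order`, `point_group`, `jammed`, `alias`
#'   (`NA`, see [`configuration_classes()`]), `n_labeled` (input configs in
#'   the class), and a list column `canonical` of integer vectors.
#' @examples
#' core <- build_core("icosahedral-60mer")
#' grp <- rotation_group(core)
#' rule <- exclusion_rule(3)
#' cls <- classify(enumerate_valid(core, rule, size = 4), grp, rule, core)
#' nrow(cls)              # 2 tetrahedral arrangements
#' cls$stabilizer_order   # 12, 12
#' @export
classify <- function(configs, group, rule = NULL, core) {
  stopifnot(inherits(group, "RotationGroup"), inherits(core, "CoreLattice"))
  if (group$order > 0 && length(configs)) {
    bad <- vapply(configs, function(s)
      length(s) && (min(s) < 1L || max(s) > core$n_vertices), logical(1))
    if (any(bad)) stop("configs contain vertex ids outside the lattice")
  }
  keys <- vapply(configs, function(s) occ_key(canonical_form(s, group)),
                 character(1))
  ukeys <- unique(keys)
  rows <- lapply(ukeys, function(k) {
    occ <- canonical_form(configs[[match(k, keys)]], group)
    images <- vapply(group$elements, function(e) occ_key(e$perm[occ]),
                     character(1))
    orbit <- length(unique(images))
    stab_idx <- which(images == occ_key(occ))
    pg <- point_group_label(group$elements[stab_idx])
    jam <- if (!is.null(rule)) is_jammed(occ, rule, core) else NA
    list(canonical_key = k, size = length(occ), orbit_size = orbit,
         stabilizer_order = length(stab_idx), point_group = pg,
         jammed = jam, alias = NA_character_,
         n_labeled = sum(keys == k), canonical = occ)
  })
  out <- data.frame(
    canonical_key = vapply(rows, `[[`, character(1), "canonical_key"),
    size = vapply(rows, `[[`, integer(1), "size"),
    orbit_size = vapply(rows, `[[`, integer(1), "orbit_size"),
    stabilizer_order = vapply(rows, `[[`, integer(1), "stabilizer_order"),
    point_group = vapply(rows, `[[`, character(1), "point_group"),
    jammed = vapply(rows, `[[`, logical(1), "jammed"),
    alias = vapply(rows, `[[`, character(1), "alias"),
    n_labeled = vapply(rows, `[[`, integer(1), "n_labeled"),
    stringsAsFactors = FALSE)
  out$canonical <- I(lapply(rows, `[[`, "canonical"))
  out[order(out$size, out$canonical_key), , drop = FALSE]
}

#' Name a finite proper rotation group from its element-order census
#'
#' Identifies the point group of a set of rotations (typically a stabilizer
#' subgroup returned during classification) from the orders of its elements:
#' order 1 is C1; a cyclic group of order n is Cn; a dihedral group of order
#' 2n is Dn; order 12 with eight threefold and three twofold rotations is the
#' tetrahedral group T; order 24 with the octahedral census is O; order 60 is
#' the icosahedral group I.
#'
#' @param elements list of group elements (`perm`/`mat` pairs) forming a
#'   subgroup: must contain the identity and be closed under composition.
#' @return character label, one of C1, Cn, Dn, T, O, I.
#' @export
point_group_label <- function(elements) {
  n_el <- length(elements)
  if (n_el == 0L) stop("empty element set")
  nverts <- length(elements[[1L]]$perm)
  keys <- vapply(elements, function(e) paste(e$perm, collapse = ","),
                 character(1))
  idp <- paste(seq_len(nverts), collapse = ",")
  if (!idp %in% keys) stop("element set does not contain the identity")
  # closure check (composition of permutations stays in the set)
  for (a in elements) {
    for (b in elements) {
      if (!paste(a$perm[b$perm], collapse = ",") %in% keys) {
        stop("element set is not closed under composition")
      }
    }
  }
  ords <- vapply(elements, function(e) perm_order(e$perm), integer(1))
  census <- tabulate(ords, nbins = max(ords))
  if (n_el == 1L) return("C1")
  if (n_el == 60L) return("I")
  if (n_el == 24L && census[3] == 8L && length(census) >= 4 && census[4] == 6L)
    return("O")
  if (n_el == 12L && census[3] == 8L && census[2] == 3L) return("T")
  if (max(ords) == n_el) return(paste0("C", n_el))
  if (n_el %% 2L == 0L) {
    h <- n_el %/% 2L
    if (h == 2L && census[2] == 3L) return("D2")
    if (h > 2L && max(ords) == h && census[2] >= h) return(paste0("D", h))
  }
  stop("unrecognized rotation-group census (order ", n_el, ")")
}

perm_order <- function(p) {
  q <- p
  o <- 1L
  idx <- seq_along(p)
  while (!all(q == idx)) {
    q <- p[q]
    o <- o + 1L
  }
  o
}

#' Enumerate and classify all valid occupancy configurations
#'
#' High-level driver: enumerates every valid occupancy under the rule,
#' partitions them into rotation classes, and attaches conventional aliases:
#' \itemize{
#'   \item the jammed maximal classes: if exactly two exist (the mirror pair
#'     of tetrahedral arrangements on the dodecahedral lattice at
#'     `min_distance = 3`) they are `X<s>S` and `Y<s>S` in canonical-key
#'     order; a single one is `<s>S` (e.g. `8S` at `min_distance = 2`);
#'   \item jammed classes below the maximum size ("suboptimal"): `<s>S`
#'     (numbered `<s>S.1`, `<s>S.2`, ... if several classes share a size);
#'   \item non-jammed classes that are rotational subsets of exactly one of
#'     the two maximal classes ("unsaturated"): `X<s>U` / `Y<s>U`.
#' }
#' The assignment of `X` versus `Y` to the two mirror classes is by canonical
#' order only; which of them corresponds to a particular experimentally
#' reconstructed map cannot be decided from the lattice alone.
#'
#' @inheritParams is_valid
#' @param sizes optional integer vector restricting the returned classes to
#'   these occupancy sizes (the enumeration used for alias context is always
#'   complete).
#' @param group optional precomputed [`rotation_group()`].
#' @return the [`classify()`] data frame with `alias` filled in.
#' @export
configuration_classes <- function(core, rule, sizes = NULL, group = NULL) {
  stopifnot(inherits(core, "CoreLattice"), inherits(rule, "ExclusionRule"))
  if (is.null(group)) group <- rotation_group(core)
  cls <- classify(enumerate_valid(core, rule), group, rule, core)
  cls$alias <- assign_aliases(cls, group)
  if (!is.null(sizes)) cls <- cls[cls$size %in% sizes, , drop = FALSE]
  cls
}

assign_aliases <- function(cls, group) {
  alias <- rep(NA_character_, nrow(cls))
  max_size <- max(cls$size)
  max_jam <- which(cls$size == max_size & cls$jammed)
  two_max <- length(max_jam) == 2L
  if (two_max) {
    ord <- max_jam[order(cls$canonical_key[max_jam])]
    alias[ord] <- paste0(c("X", "Y"), max_size, "S")
  } else if (length(max_jam) == 1L) {
    alias[max_jam] <- paste0(max_size, "S")
  }
  for (s in setdiff(unique(cls$size[cls$jammed]), max_size)) {
    idx <- which(cls$size == s & cls$jammed)
    idx <- idx[order(cls$canonical_key[idx])]
    alias[idx] <- if (length(idx) == 1L) paste0(s, "S") else
      paste0(s, "S.", seq_along(idx))
  }
  if (two_max) {
    xy <- cls$canonical[max_jam[order(cls$canonical_key[max_jam])]]
    for (i in which(!cls$jammed & cls$size > 0L)) {
      inx <- orbit_subset_of(cls$canonical[[i]], xy[[1L]], group)
      iny <- orbit_subset_of(cls$canonical[[i]], xy[[2L]], group)
      if (inx && !iny) alias[i] <- paste0("X", cls$size[i], "U")
      if (iny && !inx) alias[i] <- paste0("Y", cls$size[i], "U")
    }
  }
  alias
}

# is some rotation image of `occ` a subset of the vertex set `target`?
orbit_subset_of <- function(occ, target, group) {
  for (e in group$elements) {
    if (all(e$perm[occ] %in% target)) return(TRUE)
  }
  FALSE
}
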