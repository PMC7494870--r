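# Shared fixtures (built once per test run) and independent brute-force
# oracles used to cross-check the package's group-theoretic shortcuts.

dodeca <- build_core("icosahedral-60mer")
dodeca_group <- rotation_group(dodeca)
cube <- build_core("octahedral-24mer")
cube_group <- rotation_group(cube)

# brute-force validity: direct pairwise distance check, no pruning
bf_valid <- function(occ, md, core) {
  if (length(occ) < 2L) return(TRUE)
  all(utils::combn(occ, 2, function(p) core$dist[p[1], p[2]]) >= md)
}

# brute-force enumeration over all subsets of a given size
bf_enumerate <- function(core, md, size) {
  if (size == 0L) return(list(integer(0)))
  sets <- utils::combn(core$n_vertices, size, simplify = FALSE)
  Filter(function(s) bf_valid(s, md, core), sets)
}

# naive pairwise orbit partition: two sets are equivalent iff some group
# element maps one onto the other (no canonical forms involved)
bf_orbit_partition <- function(configs, group) {
  reps <- list()
  assignment <- integer(length(configs))
  equivalent <- function(a, b) {
    sb <- sort(b)
    for (e in group$elements) {
      if (identical(sort(e$perm[a]), sb)) return(TRUE)
    }
    FALSE
  }
  for (i in seq_along(configs)) {
    hit <- 0L
    for (j in seq_along(reps)) {
      if (equivalent(configs[[i]], reps[[j]])) {
        hit <- j
        break
      }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- configs[[i]]
      hit <- length(reps)
    }
    assignment[i] <- hit
  }
  list(representatives = reps, assignment = assignment)
}

# plain-state jamming recursion: memoized on raw sorted states, no group
# theory anywhere; returns terminal-state probabilities keyed by the sorted
# occupied set, plus the number of distinct states expanded
oracle_jamming <- function(core, md) {
  memo <- new.env(parent = emptyenv())
  rec <- function(occ) {
    key <- paste0("s", paste(occ, collapse = ","))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    free <- setdiff(seq_len(core$n_vertices), occ)
    add <- free[vapply(free, function(v) length(occ) == 0L ||
                         all(core$dist[v, occ] >= md), logical(1))]
    if (length(add) == 0L) {
      res <- stats::setNames(1, paste(occ, collapse = ","))
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
  list(probs = probs, n_states = length(ls(memo)))
}

# aggregate oracle terminal-state probabilities into canonical classes
oracle_class_probs <- function(oracle, group) {
  states <- lapply(strsplit(names(oracle$probs), ","), as.integer)
  keys <- vapply(states, function(s)
    corelattice:::occ_key(canonical_form(s, group)), character(1))
  probs <- tapply(oracle$probs, keys, sum)
  stats::setNames(as.vector(probs), names(probs))
}

# one pentagonal face of the dodecahedron (any shortest cycle: girth 5)
dodeca_face <- function() {
  g <- igraph::graph_from_edgelist(dodeca$edges, directed = FALSE)
  sort(as.integer(igraph::girth(g)$circle))
}

write_tetrahedron_json <- function(path) {
  coords <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  edges <- t(utils::combn(0:3, 2))
  jsonlite::write_json(list(name = "tetrahedron",
                            coords = coords, edges = edges),
                       path, digits = 12)
  path
}
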