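# Binding-stoichiometry ledger derived from lattice geometry.

#' Stoichiometry report for interior-protein binding
#'
#' Translates the lattice geometry and a binding mode into the maximum
#' simultaneous binding stoichiometry of the interior protein (PX):
#' \describe{
#'   \item{`"edge_monomer"`}{monomeric binding, one binding helix per bridge
#'     pocket: the bound-monomer maximum is the number of edges (30 on the
#'     icosahedral 60-mer, giving the 2:1 E2:PX ratio seen for core-binding
#'     domain fragments).}
#'   \item{`"vertex_trimer"`}{trimeric binding, one trimer per vertex
#'     consuming its three incident pockets, subject to the exclusion rule:
#'     the oligomer maximum is the largest valid occupancy found by
#'     exhaustive enumeration (8 trimers = 24 monomers at
#'     `min_distance = 2`; 4 trimers = 12 monomers for volume-occluding
#'     trimers at `min_distance = 3`, the 60:12 = 5:1 ratio).}
#' }
#' All counts are computed from the lattice and the occupancy enumeration;
#' none are hard-coded.
#'
#' @param core a [`build_core()`] lattice.
#' @param binding_mode `"edge_monomer"` or `"vertex_trimer"`.
#' @param min_distance exclusion threshold for `"vertex_trimer"` mode
#'   (ignored for `"edge_monomer"`); default 3, the volume-occluding rule.
#' @return a `StoichiometryReport` list: `core`, `core_subunits`,
#'   `binding_sites`, `binding_mode`, `min_distance`, `max_bound_oligomers`,
#'   `max_bound_monomers`, `core_to_px_ratio` (reduced integer pair).
#' @examples
#' core <- build_core("icosahedral-60mer")
#' stoichiometry_report(core, "edge_monomer")$max_bound_monomers        # 30
#' stoichiometry_report(core, "vertex_trimer", 3)$max_bound_monomers   # 12
#' @export
stoichiometry_report <- function(core,
                                 binding_mode = c("edge_monomer", "vertex_trimer"),
                                 min_distance = 3L) {
  stopifnot(inherits(core, "CoreLattice"))
  binding_mode <- match.arg(binding_mode)
  subunits <- core$n_vertices * core$n_subunits_per_vertex
  sites <- nrow(core$edges)
  if (binding_mode == "edge_monomer") {
    olig <- sites
    olig_size <- 1L
    md <- NA_integer_
  } else {
    md <- as.integer(min_distance)
    rule <- exclusion_rule(md)
    olig <- max(lengths(enumerate_valid(core, rule)))
    olig_size <- core$n_subunits_per_vertex
  }
  monomers <- olig * olig_size
  g <- gcd_int(subunits, monomers)
  structure(
    list(core = core$name,
         core_subunits = subunits,
         binding_sites = sites,
         binding_mode = binding_mode,
         min_distance = md,
         max_bound_oligomers = as.integer(olig),
         max_bound_monomers = as.integer(monomers),
         core_to_px_ratio = c(subunits %/% g, monomers %/% g)),
    class = "StoichiometryReport")
}

#' Annotate literature binding ratios against the lattice model
#'
#' Prior biochemical measurements reported core-subunit:PX ratios of 2:1,
#' 4:1 and 5:1.  This helper states, per ratio, the implied number of bound
#' PX monomers on the given core and which geometric binding mode of
#' [`stoichiometry_report()`] reproduces it: 2:1 (30 monomers on the 60-mer)
#' is monomeric binding saturating every bridge pocket, and 5:1 (12
#' monomers) is volume-occluding trimeric binding.  The 4:1 ratio (15
#' monomers) has no counterpart in this lattice model and is flagged
#' unexplained; non-occluding trimeric binding (24 monomers, 5:2) sits
#' between the literature values.
#'
#' @param core a [`build_core()`] lattice.
#' @param ratios integer core:PX ratios to annotate (default the three
#'   literature values).
#' @return data frame with columns `ratio`, `implied_monomers`,
#'   `mechanism`, `explained`.
#' @export
literature_ratios <- function(core, ratios = c(2L, 4L, 5L)) {
  stopifnot(inherits(core, "CoreLattice"))
  subunits <- core$n_vertices * core$n_subunits_per_vertex
  mono <- stoichiometry_report(core, "edge_monomer")$max_bound_monomers
  tri2 <- stoichiometry_report(core, "vertex_trimer", 2)$max_bound_monomers
  tri3 <- stoichiometry_report(core, "vertex_trimer", 3)$max_bound_monomers
  implied <- subunits / ratios
  mechanism <- vapply(implied, function(m) {
    if (m == mono) "edge_monomer (one PX helix per bridge pocket)"
    else if (m == tri2) "vertex_trimer, min_distance 2 (non-occluding trimers)"
    else if (m == tri3) "vertex_trimer, min_distance 3 (volume-occluding trimers)"
    else "none (unexplained by the lattice model)"
  }, character(1))
  data.frame(ratio = sprintf("%d:1", ratios),
             implied_monomers = implied,
             mechanism = mechanism,
             explained = !startsWith(mechanism, "none"),
             stringsAsFactors = FALSE)
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' @export
print.StoichiometryReport <- function(x, ...) {
  cat(sprintf("StoichiometryReport for \"%s\" (%s mode)\n", x$core, x$binding_mode))
  cat(sprintf("  core subunits:        %d\n", x$core_subunits))
  cat(sprintf("  bridge binding sites: %d\n", x$binding_sites))
  if (!is.na(x$min_distance))
    cat(sprintf("  exclusion distance:   %d\n", x$min_distance))
  cat(sprintf("  max bound oligomers:  %d\n", x$max_bound_oligomers))
  cat(sprintf("  max bound monomers:   %d\n", x$max_bound_monomers))
  cat(sprintf("  core:PX ratio:        %d:%d\n",
              x$core_to_px_ratio[1], x$core_to_px_ratio[2]))
  invisible(x)
}
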