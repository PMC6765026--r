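# Inverse problem: match observed capsid observables (protein totals, MCP/mCP
# split, capsomer counts, radius pairs) against the design catalog.

#' Observed capsid quantities
#'
#' Container for the observables used by [classify_by_counts()].  All fields
#' are optional but at least one must be given; counts are matched exactly
#' (the theory is exact), radii only enter ratio tests.
#'
#' @param n_total total number of capsid proteins.
#' @param n_MCP,n_mCP major / minor capsid protein counts.
#' @param pentamers,hexamers,trimers,dimers observed capsomer counts.
#' @param tiles observed tile count (dual tilings).
#' @param radius_nm average capsid radius in nm.
#' @return Object of class `capsid_observables`.
#' @export
#' @examples
#' capsid_observables(n_total = 1080, n_MCP = 540)   # phage Basilisk
capsid_observables <- function(n_total = NA, n_MCP = NA, n_mCP = NA,
                               pentamers = NA, hexamers = NA, trimers = NA,
                               dimers = NA, tiles = NA, radius_nm = NA) {
  obs <- list(n_total = n_total, n_MCP = n_MCP, n_mCP = n_mCP,
              pentamers = pentamers, hexamers = hexamers, trimers = trimers,
              dimers = dimers, tiles = tiles, radius_nm = radius_nm)
  counts <- obs[setdiff(names(obs), "radius_nm")]
  if (all(vapply(obs, function(x) is.na(x) || is.null(x), logical(1))))
    stop("at least one observable must be provided")
  for (nm in names(counts)) {
    x <- counts[[nm]]
    if (!is.na(x) && (!is.numeric(x) || x < 0 || x != round(x)))
      stop(sprintf("observable '%s' must be a non-negative integer", nm))
  }
  if (!is.na(radius_nm) && (!is.numeric(radius_nm) || radius_nm <= 0))
    stop("radius_nm must be a positive real")
  if (!is.na(n_total) && !is.na(n_MCP) && !is.na(n_mCP) &&
      n_total != n_MCP + n_mCP)
    stop(sprintf("contradictory observables: n_total (%d) != n_MCP + n_mCP (%d)",
                 n_total, n_MCP + n_mCP))
  structure(obs, class = "capsid_observables")
}

#' Classify observed counts against the design catalog
#'
#' Scans [enumerate_designs()] and returns every design whose predicted
#' stoichiometry and census agree exactly with all the provided count fields.
#' Pentamer counts match only icosahedral designs (12 pentamers; with
#' `portal = TRUE` an observed count of 11 is accepted as 12 pentamer
#' positions, one occupied by a portal).  Dimer counts match rhomb-tiling
#' designs (`n_total / 2` dimers); tile counts match dual designs.  An empty
#' result is a valid outcome: e.g. 1080 proteins under `ck_strict` alone has
#' no hit because T = 18 is not of the form `h^2 + hk + k^2`.
#'
#' @param obs a [capsid_observables()] (or a plain list of the same fields).
#' @param max_T search bound on the scaled T-number.
#' @param symmetry,kinds,conventions restrict the catalog scan.
#' @param portal accept 11 observed pentamers as 12 pentamer positions.
#' @param n_per_tile proteins per floret tile.
#' @return A data frame of hits (catalog rows plus a `matched_fields` column),
#'   sorted by scaled T-number; zero rows if nothing matches.
#' @export
#' @examples
#' classify_by_counts(capsid_observables(n_total = 1080, n_MCP = 540))
classify_by_counts <- function(obs, max_T = 50,
                               symmetry = c("icosahedral", "octahedral"),
                               kinds = LATTICE_KINDS, conventions = NULL,
                               portal = FALSE, n_per_tile = 6) {
  if (!inherits(obs, "capsid_observables"))
    obs <- do.call(capsid_observables, obs)
  cat_df <- enumerate_designs(max_T, symmetry = symmetry, kinds = kinds,
                              conventions = conventions,
                              n_per_tile = n_per_tile)
  rhomb <- c("rhomb_order_2", "rhomb_order_4", "rhomb_order_6")
  hit <- rep(TRUE, nrow(cat_df))
  matched <- rep("", nrow(cat_df))
  note <- function(ok, field) {
    hit <<- hit & ok
    matched[ok] <<- paste(matched[ok], field)
  }
  if (!is.na(obs$n_total)) note(cat_df$n_total == obs$n_total, "n_total")
  if (!is.na(obs$n_MCP))   note(cat_df$n_MCP == obs$n_MCP, "n_MCP")
  if (!is.na(obs$n_mCP))   note(cat_df$n_mCP == obs$n_mCP, "n_mCP")
  if (!is.na(obs$pentamers)) {
    ok <- cat_df$symmetry == "icosahedral" &
      (cat_df$vertex_polygons == obs$pentamers |
         (portal & obs$pentamers == 11L & cat_df$vertex_polygons == 12L))
    note(ok, "pentamers")
  }
  if (!is.na(obs$hexamers))
    note(!cat_df$dual & cat_df$hexagons == obs$hexamers, "hexamers")
  if (!is.na(obs$trimers))
    note(!cat_df$dual & cat_df$triangles == obs$trimers, "trimers")
  if (!is.na(obs$dimers))
    note(cat_df$convention %in% rhomb & cat_df$n_total == 2L * obs$dimers,
         "dimers")
  if (!is.na(obs$tiles))
    note(cat_df$dual & cat_df$dual_tiles == obs$tiles, "tiles")
  hits <- cat_df[hit, , drop = FALSE]
  hits$matched_fields <- trimws(matched[hit])
  hits <- hits[order(hits$T_scaled), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("classification_hits", class(hits))
  hits
}

#' @export
print.classification_hits <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("no matching design\n")
    return(invisible(x))
  }
  df <- as.data.frame(x)[, c("T_label", "symmetry", "dual", "convention",
                             "n_MCP", "n_mCP", "n_total", "matched_fields")]
  print(df, row.names = FALSE)
  invisible(x)
}

#' Radius-ratio hypothesis test
#'
#' Compares an observed radius ratio `r_a / r_b` with the ratio predicted for
#' two designs under equal per-protein footprints
#' (`sqrt(alpha_a T_a / (alpha_b T_b))`), reporting the relative deviation.
#' No accept/reject verdict is issued; the deviation is reported as is.
#'
#' @param r_a_nm,r_b_nm positive radii (nm).
#' @param design_a,design_b the two candidate [capsid_design()]s.
#' @return Object of class `ratio_test`: list with `observed_ratio`,
#'   `predicted_ratio` and `relative_deviation`
#'   (`|observed - predicted| / predicted`).
#' @export
#' @examples
#' # Tobacco ringspot (15.4 nm) vs Pariacoto virus (17.2 nm)
#' radius_ratio_test(15.4, 17.2,
#'                   capsid_design("rhombi", 1, 0, dual = TRUE),
#'                   capsid_design("hex", 1, 1, dual = TRUE))
radius_ratio_test <- function(r_a_nm, r_b_nm, design_a, design_b) {
  if (!is.numeric(r_a_nm) || !is.numeric(r_b_nm) || r_a_nm <= 0 || r_b_nm <= 0)
    stop("radii must be positive reals")
  pred <- size_scaling(design_a, design_b)$radius_ratio
  obs <- r_a_nm / r_b_nm
  structure(list(observed_ratio = obs, predicted_ratio = pred,
                 relative_deviation = abs(obs - pred) / pred,
                 design_a = design_a, design_b = design_b),
            class = "ratio_test")
}

#' @export
print.ratio_test <- function(x, ...) {
  cat(sprintf("observed ratio %.4f, predicted %.4f, relative deviation %.2f%%\n",
              x$observed_ratio, x$predicted_ratio,
              100 * x$relative_deviation))
  invisible(x)
}
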