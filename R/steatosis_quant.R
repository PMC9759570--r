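#' Classified tile grid from a slide region
#'
#' Square image tiles classified into microvesicular steatosis,
#' macrovesicular steatosis, non-steatotic hepatocytes, or vessel lumen
#' (excluded from surface percentages). At least 30 tiles per image are
#' required for a stable estimate.
#'
#' @param labels Character vector of tile labels, each one of
#'   \code{"micro"}, \code{"macro"}, \code{"non_steatotic"},
#'   \code{"lumen"}.
#' @param tile_area Uniform tile area (arbitrary units).
#' @return An object of class \code{tile_grid}.
#' @export
tile_grid <- function(labels, tile_area = 1) {
  vocab <- c("micro", "macro", "non_steatotic", "lumen")
  labels <- as.character(labels)
  if (length(labels) < 30) {
    stop("need at least 30 tiles per image, got ", length(labels))
  }
  bad <- setdiff(unique(labels), vocab)
  if (length(bad)) stop("unknown tile labels: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, tile_area = tile_area),
            class = "tile_grid")
}

#' Steatosis surface percentages
#'
#' @param micro_pct,macro_pct Surface percentage covered by micro- and
#'   macrovesicular steatotic hepatocytes, in \[0, 100\].
#' @param lipid_droplet_pct Optional surface percentage covered by lipid
#'   droplets (from droplet-event masks).
#' @return An object of class \code{steatosis_surfaces}; the field
#'   \code{total_steatotic_pct} is always \code{micro_pct + macro_pct}.
#' @export
steatosis_surfaces <- function(micro_pct, macro_pct,
                               lipid_droplet_pct = NA_real_) {
  stopifnot(micro_pct >= 0, macro_pct >= 0,
            micro_pct + macro_pct <= 100 + 1e-9)
  structure(list(
    micro_pct = micro_pct,
    macro_pct = macro_pct,
    total_steatotic_pct = micro_pct + macro_pct,
    lipid_droplet_pct = lipid_droplet_pct
  ), class = "steatosis_surfaces")
}

#' Aggregate classified tiles into surface percentages
#'
#' Percentages are taken over non-lumen tiles only (vessel lumina are
#' excluded): micro_pct = #micro / (#micro + #macro + #non_steatotic) x
#' 100, and likewise for the other classes. The total steatotic surface is
#' the sum of the micro and macro percentages.
#'
#' @param grid A \code{\link{tile_grid}}.
#' @return A \code{\link{steatosis_surfaces}}.
#' @export
aggregate_tiles <- function(grid) {
  stopifnot(inherits(grid, "tile_grid"))
  n_micro <- sum(grid$labels == "micro")
  n_macro <- sum(grid$labels == "macro")
  n_non <- sum(grid$labels == "non_steatotic")
  denom <- n_micro + n_macro + n_non
  if (denom == 0) stop("all tiles are lumen: no tissue to quantify")
  steatosis_surfaces(micro_pct = 100 * n_micro / denom,
                     macro_pct = 100 * n_macro / denom)
}

#' Clinical severity grade from the fat-laden surface
#'
#' The conventional histopathological grading of the relative surface
#' covered by fat-laden hepatocytes: below 33\% is mild, 33-66\% moderate,
#' above 66\% severe.
#'
#' @param fat_laden_pct Percentage(s) in \[0, 100\]. Vectorized.
#' @return Character vector of grades.
#' @export
severity_grade <- function(fat_laden_pct) {
  stopifnot(is.numeric(fat_laden_pct))
  if (any(fat_laden_pct < 0 | fat_laden_pct > 100)) {
    stop("fat-laden surface percentage must lie in [0, 100]")
  }
  ifelse(fat_laden_pct < 33, "mild",
         ifelse(fat_laden_pct <= 66, "moderate", "severe"))
}

#' Micro-to-macrovesicular steatosis ratio
#'
#' Ratio of the microvesicular to the macrovesicular surface, rounded
#' half-up to one decimal to match the conventional "x.y:1" statement.
#'
#' @param micro_pct,macro_pct Surface percentages; \code{macro_pct} must
#'   be positive.
#' @return Ratio rounded to one decimal.
#' @export
micro_macro_ratio <- function(micro_pct, macro_pct) {
  stopifnot(is.numeric(micro_pct), is.numeric(macro_pct))
  if (any(macro_pct <= 0)) {
    stop("macro_pct must be positive to form a ratio")
  }
  round_half_up(micro_pct / macro_pct, digits = 1)
}

#' Lobe-averaged steatosis surfaces
#'
#' Averages per-lobe surface percentages into a whole-liver summary. By
#' default each lobe is weighted by its area, so the result reflects the
#' total surface covered across lobes; \code{weighted = FALSE} gives the
#' plain per-lobe mean.
#'
#' @param per_lobe List of \code{\link{steatosis_surfaces}}, one per lobe.
#' @param areas Positive lobe areas, same length as \code{per_lobe}.
#' @param weighted Use area weights (default) or a plain mean.
#' @return A \code{\link{steatosis_surfaces}} of the averaged fields.
#' @export
mean_across_lobes <- function(per_lobe, areas = rep(1, length(per_lobe)),
                              weighted = TRUE) {
  stopifnot(is.list(per_lobe), length(per_lobe) >= 1)
  if (length(areas) != length(per_lobe)) {
    stop("areas and per_lobe must have the same length")
  }
  if (any(areas <= 0)) stop("lobe areas must be positive")
  w <- if (weighted) areas / sum(areas) else rep(1 / length(areas),
                                                 length(areas))
  field <- function(nm) {
    sum(w * vapply(per_lobe, function(s) s[[nm]], numeric(1)))
  }
  steatosis_surfaces(micro_pct = field("micro_pct"),
                     macro_pct = field("macro_pct"),
                     lipid_droplet_pct = field("lipid_droplet_pct"))
}
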