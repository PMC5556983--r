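#' Abundance-category boundaries from the reference-point FPKM distribution
#'
#' The four cut points P50, P75, P90 and P99 (linear-interpolation
#' quantiles) of the N_0 FPKM distribution, delimiting abundance categories
#' I (below median) to V (above the 99th percentile).
#'
#' @param n0_values Numeric vector of reference-point FPKM values.
#' @return Named numeric vector of the four boundaries.
#' @export
category_boundaries <- function(n0_values) {
  if (!length(n0_values)) stop("empty abundance vector")
  if (length(n0_values) < 100L)
    warning("fewer than 100 values: percentile boundaries will be unstable")
  b <- stats::quantile(n0_values, probs = c(0.5, 0.75, 0.90, 0.99),
                       type = 7, names = FALSE)
  if (length(unique(b)) == 1L)
    warning("degenerate abundance distribution: all category boundaries equal")
  stats::setNames(b, c("P50", "P75", "P90", "P99"))
}

#' Assign abundance categories
#'
#' Categories I-V by the percentile boundaries; a value equal to a cut point
#' goes to the higher category.
#'
#' @param fpkm Numeric vector of abundances (non-negative).
#' @param boundaries Output of [category_boundaries()].
#' @return Factor with levels `I` .. `V`.
#' @export
categorize <- function(fpkm, boundaries) {
  if (any(fpkm < 0)) stop("negative abundance value")
  idx <- 1L + rowSums(outer(fpkm, unname(boundaries), ">="))
  factor(c("I", "II", "III", "IV", "V")[idx],
         levels = c("I", "II", "III", "IV", "V"))
}

# diverging colour for a capped log2-FC value: white inside the
# not-responsive band, red gradient up, blue gradient down, saturated at cap
fc_color <- function(fc, threshold = 1, cap = 4) {
  up <- grDevices::colorRamp(c("#FDDBC7", "#B2182B"))
  down <- grDevices::colorRamp(c("#D1E5F0", "#2166AC"))
  vapply(fc, function(v) {
    if (is.na(v)) return("#FFFFFF")
    if (abs(v) <= threshold) return("#FFFFFF")
    frac <- min((abs(v) - threshold) / (cap - threshold), 1)
    rgb <- if (v > 0) up(frac) else down(frac)
    grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
  }, character(1))
}

#' Render abundance/fold-change pictograms to SVG with a TSV companion
#'
#' One pictogram row per locus: the predicted localization letter
#' (C/M/S/O/NA), the abundance category as a Roman numeral (bold when the
#' gene is likely not fragmented), and three stage boxes (e-N, l-N, r+N
#' frames) holding one bar per time point coloured by the capped log2 fold
#' change — red up, blue down, white inside the not-responsive band
#' (|log2-FC| <= 1), an "NA" tag where the abundance fell below the
#' reliability floor. The TSV carries the identical values machine-readably.
#'
#' @param loci Locus ids to render (must exist in all inputs).
#' @param fc A `fragtx_fc` object.
#' @param categories Named factor from [categorize()] (names = locus ids).
#' @param localizations Named character vector (C/M/S/O/NA per locus).
#' @param fragment_flags Named logical vector: `TRUE` when the locus is
#'   likely fragmented (numeral rendered non-bold).
#' @param out_prefix Output path prefix; writes `<prefix>.svg` and
#'   `<prefix>.tsv`.
#' @param cap Display cap (log2 units).
#' @param threshold Not-responsive band half-width (log2 units).
#' @return Invisible list with the two file paths.
#' @export
render_pictograms <- function(loci, fc, categories, localizations,
                              fragment_flags, out_prefix, cap = 4,
                              threshold = 1) {
  for (nm in list(rownames(fc$log2fc), names(categories),
                  names(localizations), names(fragment_flags))) {
    absent <- setdiff(loci, nm)
    if (length(absent))
      stop("locus missing from an input: ", paste(absent, collapse = ", "))
  }
  stages <- stage_definition()
  stage_cols <- c("e-N" = "#E69F00", "l-N" = "#8C510A", "r+N" = "#1B7837")
  tps <- colnames(fc$log2fc)
  capped <- cap_for_display(fc$log2fc[loci, , drop = FALSE], cap = cap)

  # companion TSV
  tsv <- data.frame(locus_id = loci,
                    localization = unname(localizations[loci]),
                    category = as.character(categories[loci]),
                    fragmented = unname(fragment_flags[loci]),
                    stringsAsFactors = FALSE)
  for (tp in tps) {
    v <- capped$value[loci, tp]
    tsv[[paste0("log2fc_", tp)]] <- ifelse(fc$na_mask[loci, tp], NA, v)
    tsv[[paste0("high_", tp)]] <- ifelse(fc$na_mask[loci, tp], NA,
                                         capped$highly_regulated[loci, tp])
  }
  tsv_path <- paste0(out_prefix, ".tsv")
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  # SVG geometry
  bar_w <- 14; bar_h <- 18; gap <- 6; row_h <- bar_h + 10
  left <- 120
  width <- left + length(tps) * bar_w + 2 * length(stages) * gap + 40
  height <- 30 + length(loci) * row_h
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d">',
                   width, height))
  for (i in seq_along(loci)) {
    id <- loci[i]
    y <- 20 + (i - 1L) * row_h
    bold <- if (isTRUE(fragment_flags[[id]])) "normal" else "bold"
    svg <- c(svg,
      sprintf('<text x="4" y="%d" font-size="10">%s</text>', y + 13L, id),
      sprintf('<text x="%d" y="%d" font-size="11">%s</text>', left - 44L,
              y + 13L, localizations[[id]]),
      sprintf('<text x="%d" y="%d" font-size="11" font-weight="%s">%s</text>',
              left - 26L, y + 13L, bold, as.character(categories[[id]])))
    x <- left
    for (s in names(stages)) {
      box_w <- length(stages[[s]]) * bar_w
      svg <- c(svg, sprintf(
        '<rect x="%d" y="%d" width="%d" height="%d" fill="none" stroke="%s" stroke-width="2"/>',
        x, y, box_w, bar_h, stage_cols[[s]]))
      for (tp in stages[[s]]) {
        if (fc$na_mask[id, tp]) {
          svg <- c(svg, sprintf(
            '<text x="%d" y="%d" font-size="7">NA</text>', x + 1L, y + 12L))
        } else {
          col <- fc_color(capped$value[id, tp], threshold = threshold, cap = cap)
          svg <- c(svg, sprintf(
            '<rect x="%d" y="%d" width="%d" height="%d" fill="%s" stroke="#888" stroke-width="0.5"/>',
            x, y, bar_w, bar_h, col))
        }
        x <- x + bar_w
      }
      x <- x + gap
    }
  }
  svg <- c(svg, "</svg>")
  svg_path <- paste0(out_prefix, ".svg")
  writeLines(svg, svg_path)
  invisible(list(svg = svg_path, tsv = tsv_path))
}
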