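#' ROI templates for the three high-order networks
#'
#' An ROI template is a data frame with one row per spherical region of
#' interest and columns `name`, `network` (one of `"DMN"`, `"DAN"`, `"ECN"`),
#' `x`, `y`, `z` (sphere centre, mm, RAS+ template space), `radius` (mm) and
#' `hemi` (`"L"`, `"R"` or `"M"` for midline). It drives time-course
#' extraction, network-level aggregation and cluster-purity scoring.
#'
#' @name roi_template
NULL

#' Default 19-node parcellation of the DMN, DAN and ECN
#'
#' Returns the default template: 19 spheres of 8 mm radius covering the
#' default mode network (6 nodes: posterior cingulate/precuneus, medial
#' prefrontal cortex, bilateral lateral parietal cortex, bilateral inferior
#' temporal gyrus), the dorsal attention network (8 nodes: bilateral frontal
#' eye fields, posterior and anterior intraparietal sulcus, middle temporal
#' area) and the executive control network (5 nodes: dorsomedial prefrontal
#' cortex, bilateral anterior prefrontal cortex, bilateral superior parietal
#' cortex).
#'
#' Centre coordinates are reconstructed from the widely used adult
#' resting-state landmark set of Raichle (2011); the exact coordinates used
#' for any given infant study (after alignment to age-specific structural
#' templates) may differ, so every analysis function accepts a user-supplied
#' template read with [read_roi_template()]. Two anterior-intraparietal /
#' superior-parietal sphere pairs in this landmark set lie closer than twice
#' the 8 mm radius; [validate_roi_template()] warns (rather than fails) on
#' overlap, and only volumetric rendering, where overlap would make voxel
#' ownership ambiguous, refuses overlapping templates.
#'
#' @param radius sphere radius in mm (default 8).
#' @return an ROI template data frame (class `roi_template`).
#' @export
default_roi_template <- function(radius = 8) {
  tpl <- data.frame(
    name = c("PCC/Prec", "mPFC", "lPC L", "lPC R", "ITG L", "ITG R",
             "FEF L", "FEF R", "pIPS L", "pIPS R", "aIPS L", "aIPS R",
             "MT L", "MT R",
             "dmPFC", "aPFC L", "aPFC R", "SPC L", "SPC R"),
    network = c(rep("DMN", 6), rep("DAN", 8), rep("ECN", 5)),
    x = c(0, -1, -46, 49, -61, 58,
          -29, 29, -26, 26, -44, 41, -50, 53,
          0, -44, 44, -50, 50),
    y = c(-52, 54, -66, -63, -24, -24,
          -9, -9, -66, -66, -39, -39, -66, -63,
          24, 45, 45, -51, -51),
    z = c(27, 27, 30, 33, -9, -9,
          54, 54, 48, 48, 45, 45, -6, -6,
          46, 0, 0, 45, 45),
    radius = radius,
    hemi = c("M", "M", "L", "R", "L", "R",
             "L", "R", "L", "R", "L", "R", "L", "R",
             "M", "L", "R", "L", "R"),
    stringsAsFactors = FALSE
  )
  class(tpl) <- c("roi_template", "data.frame")
  validate_roi_template(tpl, warn_overlap = FALSE)
  tpl
}

#' Validate an ROI template
#'
#' Checks column presence and types, uniqueness of ROI names, positivity of
#' radii and membership of every network label in \{DMN, DAN, ECN\}.
#' Optionally warns when any two spheres overlap (centre distance smaller
#' than the sum of radii).
#'
#' @param template an ROI template data frame.
#' @param warn_overlap warn on overlapping sphere pairs (default TRUE).
#' @return the template, invisibly; errors describe the first violation.
#' @export
validate_roi_template <- function(template, warn_overlap = TRUE) {
  needed <- c("name", "network", "x", "y", "z", "radius")
  missing_cols <- setdiff(needed, names(template))
  if (length(missing_cols))
    stop("ROI template is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(template$name))
    stop("ROI template has duplicated ROI names")
  if (!all(template$network %in% c("DMN", "DAN", "ECN")))
    stop("ROI network labels must be one of DMN, DAN, ECN")
  if (!all(is.finite(template$radius)) || any(template$radius <= 0))
    stop("ROI radii must be positive and finite")
  counts <- table(template$network)
  if (length(counts) < 2)
    stop("ROI template must cover at least two networks")
  ov <- overlapping_roi_pairs(template)
  if (warn_overlap && nrow(ov) > 0)
    warning("overlapping ROI spheres: ",
            paste(paste(ov$a, "/", ov$b), collapse = "; "))
  invisible(template)
}

#' @keywords internal
overlapping_roi_pairs <- function(template) {
  xyz <- as.matrix(template[, c("x", "y", "z")])
  n <- nrow(xyz)
  a <- character(0); b <- character(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (d < template$radius[i] + template$radius[j]) {
          a <- c(a, template$name[i]); b <- c(b, template$name[j])
        }
      }
    }
  }
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

#' Synthetic well-separated ROI template
#'
#' Builds a template with the same 19 names and network labels as
#' [default_roi_template()] but with centres placed on a coarse cubic
#' lattice, guaranteeing pairwise non-overlapping spheres. Intended for
#' volumetric round-trip testing, where overlap is not allowed; it carries no
#' anatomical meaning (hence "synthetic").
#'
#' @param spacing lattice spacing in mm between neighbouring centres
#'   (default 30, comfortably above twice the default radius).
#' @param radius sphere radius in mm (default 8).
#' @return an ROI template data frame.
#' @export
synthetic_spaced_template <- function(spacing = 30, radius = 8) {
  tpl <- default_roi_template(radius = radius)
  n <- nrow(tpl)
  side <- ceiling(n^(1 / 3))
  idx <- seq_len(n) - 1L
  tpl$x <- (idx %% side) * spacing
  tpl$y <- ((idx %/% side) %% side) * spacing
  tpl$z <- (idx %/% (side * side)) * spacing
  validate_roi_template(tpl)
  tpl
}

#' Read / write ROI templates as CSV
#'
#' The on-disk format is a plain CSV with header
#' `name,network,x,y,z,radius` (an optional `hemi` column is preserved).
#'
#' @param path file path.
#' @return `read_roi_template` returns a validated template;
#'   `write_roi_template` returns `path` invisibly.
#' @export
read_roi_template <- function(path) {
  tpl <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tpl) <- c("roi_template", "data.frame")
  validate_roi_template(tpl, warn_overlap = FALSE)
  tpl
}

#' @rdname read_roi_template
#' @param template an ROI template data frame.
#' @export
write_roi_template <- function(template, path) {
  utils::write.csv(as.data.frame(template), path, row.names = FALSE)
  invisible(path)
}

#' Network sizes and pair counts implied by a template
#'
#' For the default 6/8/5 node split the unique pair counts are: within DMN
#' 15, within DAN 28, within ECN 10; between DMN-DAN 48, DMN-ECN 30,
#' DAN-ECN 40.
#'
#' @param template an ROI template.
#' @return a list with `nodes` (named counts) and `pairs` (named counts for
#'   the three within and three between sets).
#' @export
network_pair_counts <- function(template) {
  n <- table(factor(template$network, levels = c("DMN", "DAN", "ECN")))
  nodes <- as.integer(n); names(nodes) <- names(n)
  pairs <- c(
    DMN = nodes[["DMN"]] * (nodes[["DMN"]] - 1) / 2,
    DAN = nodes[["DAN"]] * (nodes[["DAN"]] - 1) / 2,
    ECN = nodes[["ECN"]] * (nodes[["ECN"]] - 1) / 2,
    `DMN-DAN` = nodes[["DMN"]] * nodes[["DAN"]],
    `DMN-ECN` = nodes[["DMN"]] * nodes[["ECN"]],
    `DAN-ECN` = nodes[["DAN"]] * nodes[["ECN"]]
  )
  list(nodes = nodes, pairs = pairs)
}
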