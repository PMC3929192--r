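#' Surface-type classes and colors
#'
#' The four sign-pair classes used to parcellate a cortical surface into
#' gyral/sulcal primitives, with their display colors:
#' \describe{
#'   \item{ELLIPTIC_GREEN}{`K_H < 0`, `K_G > 0`, SI in `[3/8, 1]` — convex
#'     dome (gyral crest).}
#'   \item{HYPERBOLIC_CYAN}{`K_H < 0`, `K_G < 0`, SI in `[1/8, 3/8]` —
#'     convex-leaning saddle (gyral ridge flank).}
#'   \item{HYPERBOLIC_BLUE}{`K_H > 0`, `K_G < 0`, SI in `[-3/8, -1/8]` —
#'     concave-leaning saddle (sulcal wall).}
#'   \item{ELLIPTIC_RED}{`K_H > 0`, `K_G > 0`, SI in `[-1, -5/8]` — concave
#'     cup (sulcal fundus).}
#' }
#' `UNCLASSIFIED` (gray) collects flat/boundary vertices, near-zero
#' curvature signs and, in strict mode, shape indices outside the class
#' interval (including the gaps `(-5/8, -3/8)` and `(-1/8, 1/8)`).
#'
#' @format character vector of hex colors named by class.
#' @export
surface_class_colors <- c(
  ELLIPTIC_GREEN = "#00FF00",
  HYPERBOLIC_CYAN = "#00FFFF",
  HYPERBOLIC_BLUE = "#0000FF",
  ELLIPTIC_RED = "#FF0000",
  UNCLASSIFIED = "#808080")

surface_class_levels <- names(surface_class_colors)

# SI interval per class, closed at both ends
surface_class_si <- list(
  ELLIPTIC_GREEN = c(3 / 8, 1),
  HYPERBOLIC_CYAN = c(1 / 8, 3 / 8),
  HYPERBOLIC_BLUE = c(-3 / 8, -1 / 8),
  ELLIPTIC_RED = c(-1, -5 / 8))

#' Classify vertices by curvature signs (and shape index)
#'
#' `sign_only` mode maps the (sign `K_H`, sign `K_G`) pair directly:
#' `(-,+)` ELLIPTIC_GREEN, `(-,-)` HYPERBOLIC_CYAN, `(+,-)` HYPERBOLIC_BLUE,
#' `(+,+)` ELLIPTIC_RED.  `strict` mode additionally requires the shape
#' index to fall inside the class interval, demoting everything else to
#' UNCLASSIFIED.  Curvatures of magnitude below `zero_tol` are treated as
#' sign zero and left UNCLASSIFIED, as near-zero curvature signs are
#' numerical noise.
#'
#' @param diffs tibble from [vertex_differentials()] (columns `k_h_signed`,
#'   `k_g`, `si`, `boundary`, `flat`), or any data frame with those columns.
#' @param mode `"sign_only"` (default, robust) or `"strict"`
#'   (classification-table faithful).
#' @param zero_tol curvature magnitude treated as zero (1/mm).
#' @return factor of classes, levels `ELLIPTIC_GREEN`, `HYPERBOLIC_CYAN`,
#'   `HYPERBOLIC_BLUE`, `ELLIPTIC_RED`, `UNCLASSIFIED`.
#' @export
classify_vertices <- function(diffs, mode = c("sign_only", "strict"),
                              zero_tol = 0) {
  mode <- match.arg(mode)
  kh <- diffs$k_h_signed
  kg <- diffs$k_g
  si <- diffs$si
  n <- length(kh)
  cls <- rep("UNCLASSIFIED", n)
  sh <- ifelse(abs(kh) <= zero_tol, 0, sign(kh))
  sg <- ifelse(abs(kg) <= zero_tol^2, 0, sign(kg))
  ok <- !is.na(kh) & !is.na(kg) & sh != 0 & sg != 0
  if (!is.null(diffs$boundary)) ok <- ok & !diffs$boundary
  if (!is.null(diffs$flat)) ok <- ok & !diffs$flat
  cls[ok & sh < 0 & sg > 0] <- "ELLIPTIC_GREEN"
  cls[ok & sh < 0 & sg < 0] <- "HYPERBOLIC_CYAN"
  cls[ok & sh > 0 & sg < 0] <- "HYPERBOLIC_BLUE"
  cls[ok & sh > 0 & sg > 0] <- "ELLIPTIC_RED"
  if (mode == "strict") {
    for (cl in names(surface_class_si)) {
      iv <- surface_class_si[[cl]]
      bad <- cls == cl & (is.na(si) | si < iv[1] | si > iv[2])
      cls[bad] <- "UNCLASSIFIED"
    }
  }
  factor(cls, levels = surface_class_levels)
}

#' Label a surface and summarize its parcellation
#'
#' Classifies every vertex, attaches colors, and computes the class
#' histogram and mixed-area-weighted area fraction per class.  The
#' `consistent` flag records whether the sign-pair class and the
#' strict-mode (shape-index interval) class agree at the vertex.
#'
#' @param mesh the `triangle_mesh` the differentials were computed on.
#' @param diffs tibble from [vertex_differentials()] for `mesh`.
#' @param mode `"sign_only"` or `"strict"` (the mode of the reported class).
#' @param zero_tol curvature magnitude treated as sign zero (1/mm); default
#'   `1e-6 / mean_edge_length(mesh)`, i.e. scale aware.
#' @return a `surface_labeling` object: list with `labels` (tibble: `vertex`,
#'   `class`, `color`, `si`, `consistent`), `histogram` (named integer),
#'   `area_fraction` (named numeric, sums to 1), `mode`, `zero_tol`.
#' @export
label_surface <- function(mesh, diffs, mode = c("sign_only", "strict"),
                          zero_tol = NULL) {
  mode <- match.arg(mode)
  if (nrow(diffs) != n_vertices(mesh))
    stop("diffs has ", nrow(diffs), " rows but mesh has ",
         n_vertices(mesh), " vertices")
  if (is.null(zero_tol)) zero_tol <- 1e-6 / mean_edge_length(mesh)
  sign_cls <- classify_vertices(diffs, "sign_only", zero_tol)
  strict_cls <- classify_vertices(diffs, "strict", zero_tol)
  cls <- if (mode == "strict") strict_cls else sign_cls
  labels <- tibble::tibble(
    vertex = seq_len(n_vertices(mesh)),
    class = cls,
    color = unname(surface_class_colors[as.character(cls)]),
    si = diffs$si,
    consistent = as.character(sign_cls) == as.character(strict_cls))
  hist <- table(cls)
  af <- tapply(diffs$a_m, cls, sum, default = 0)
  af <- af / sum(diffs$a_m)
  structure(list(labels = labels,
                 histogram = stats::setNames(as.integer(hist), names(hist)),
                 area_fraction = stats::setNames(as.numeric(af), names(af)),
                 mode = mode, zero_tol = zero_tol),
            class = "surface_labeling")
}

#' @export
print.surface_labeling <- function(x, ...) {
  cat(sprintf("<surface_labeling: %d vertices, mode = %s>\n",
              nrow(x$labels), x$mode))
  h <- x$histogram
  for (cl in names(h))
    cat(sprintf("  %-16s %6d (%5.1f%% area)\n", cl, h[[cl]],
                100 * x$area_fraction[[cl]]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a surface labeling into one row per vertex
#'
#' @param x a `surface_labeling`.
#' @param ... unused.
#' @return the per-vertex label tibble.
#' @export
tidy.surface_labeling <- function(x, ...) x$labels

#' One-row summary of a surface labeling
#'
#' @param x a `surface_labeling`.
#' @param ... unused.
#' @return a one-row tibble with per-class counts and area fractions.
#' @export
glance.surface_labeling <- function(x, ...) {
  out <- tibble::tibble(n_vertices = nrow(x$labels), mode = x$mode)
  for (cl in surface_class_levels) {
    out[[paste0("n_", tolower(cl))]] <- x$histogram[[cl]]
    out[[paste0("area_frac_", tolower(cl))]] <- x$area_fraction[[cl]]
  }
  out
}

#' Plot a surface labeling as a projected point cloud
#'
#' A quick diagnostic view: vertices scattered in two chosen coordinate
#' axes, colored by surface class.  Not a substitute for a 3D renderer, but
#' enough to see the gyral/sulcal banding on phantoms.
#'
#' @param object a `surface_labeling`.
#' @param mesh the mesh that was labeled.
#' @param axes which two coordinate axes to plot (default x, y).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.surface_labeling <- function(object, mesh, axes = c(1, 2), ...) {
  df <- tibble::tibble(
    u = mesh$vertices[, axes[1]],
    v = mesh$vertices[, axes[2]],
    class = object$labels$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   color = .data$class)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::scale_color_manual(values = surface_class_colors) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0("axis ", axes[1], " (mm)"),
                  y = paste0("axis ", axes[2], " (mm)"),
                  color = "surface type") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Label agreement across resolutions
#'
#' Measures how well a parcellation survives mesh simplification: each
#' coarse-mesh vertex is matched to its nearest full-resolution vertex and
#' the fraction of matched pairs with equal class is reported.  Pairs where
#' either side is UNCLASSIFIED are excluded from the fraction and counted
#' separately.
#'
#' @param labeling_full,labeling_coarse `surface_labeling` objects computed
#'   in the same mode.
#' @param mesh_full,mesh_coarse the meshes they were computed on.
#' @return a one-row tibble: `agreement` (fraction in `[0, 1]`),
#'   `n_compared`, `n_unclassified_pairs`, `n_coarse`.
#' @export
multires_label_agreement <- function(labeling_full, mesh_full,
                                     labeling_coarse, mesh_coarse) {
  if (nrow(labeling_full$labels) == 0L || nrow(labeling_coarse$labels) == 0L)
    stop("empty labeling")
  if (labeling_full$mode != labeling_coarse$mode)
    stop("labelings computed in different modes")
  nn <- nearest_vertex(mesh_full$vertices, mesh_coarse$vertices)
  cls_f <- as.character(labeling_full$labels$class)[nn]
  cls_c <- as.character(labeling_coarse$labels$class)
  uncl <- cls_f == "UNCLASSIFIED" | cls_c == "UNCLASSIFIED"
  n_cmp <- sum(!uncl)
  agree <- if (n_cmp > 0) mean(cls_f[!uncl] == cls_c[!uncl]) else NA_real_
  tibble::tibble(agreement = agree, n_compared = n_cmp,
                 n_unclassified_pairs = sum(uncl),
                 n_coarse = length(cls_c))
}

# for each query row, index of the nearest reference row (euclidean);
# chunked to bound memory on large meshes
nearest_vertex <- function(ref, query, chunk = 512L) {
  rn2 <- rowSums(ref^2)
  out <- integer(nrow(query))
  for (start in seq(1L, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    q <- query[idx, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn2, "+") - 2 * q %*% t(ref)
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}
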