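# Cell outlines for the desk-scale 2D reduced mode: closed CCW polygons
# (side-on cross-sections) for the four morphologies, area-matched so that
# hematocrit comparisons across shapes are well posed.

# Dense boundary polyline of the biconcave (discocyte) side-on profile.
biconcave_outline_dense <- function(d0 = 7.82, n_dense = 800) {
  R <- d0 / 2
  xs <- R * cos(seq(pi, 0, length.out = n_dense))
  top <- cbind(xs, biconcave_halfz(abs(xs), d0))
  bot <- cbind(rev(xs), -biconcave_halfz(abs(rev(xs)), d0))
  rbind(top, bot[-1, , drop = FALSE])
}

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  0.5 * sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])
}

# Resample a closed polyline to n equally spaced (by arclength) vertices.
resample_closed <- function(p, n) {
  d <- sqrt(rowSums((p[c(2:nrow(p), 1), ] - p)^2))
  keep <- d > 1e-12            # drop duplicated points
  p <- p[keep, , drop = FALSE]
  d <- d[keep]
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  tgt <- total * (seq_len(n) - 1) / n
  px <- stats::approx(s, c(p[, 1], p[1, 1]), xout = tgt)$y
  pz <- stats::approx(s, c(p[, 2], p[1, 2]), xout = tgt)$y
  cbind(px, pz)
}

#' 2D cell outline for the reduced mode
#'
#' Closed polygon (n vertices, counter-clockwise, centred on its centroid)
#' representing the side-on cross-section of an RBC of the given morphology.
#' All four shapes are rescaled to the same enclosed area (by default the
#' area of the biconcave cross-section), so suspensions of different shapes
#' compare at matched hematocrit.
#'
#' @param shape `"biconcave"`, `"elongated"`, `"granular"` or `"sickle"`.
#' @param n_vertices polygon vertex count.
#' @param area target enclosed area, um^2 (default: biconcave reference).
#' @param seed phase of the granular boundary perturbation.
#' @return n x 2 matrix with attributes `area`, `radius` (max centroid
#'   distance), `half_height`.
#' @export
make_cell_outline <- function(shape = c("biconcave", "elongated",
                                        "granular", "sickle"),
                              n_vertices = 40L, area = NULL, seed = 1L) {
  shape <- match.arg(shape)
  base <- biconcave_outline_dense()
  if (is.null(area)) area <- abs(polygon_area(base))
  p <- switch(shape,
    biconcave = base,
    elongated = cbind(1.8 * base[, 1], base[, 2] / 1.8),
    granular = {
      ph <- 2 * pi * ((as.integer(seed) %% 977) / 977)
      phi <- seq(0, 2 * pi, length.out = 721)[-721]
      r <- 1 + 0.08 * cos(5 * phi + ph) + 0.05 * sin(3 * phi - ph)
      cbind(r * cos(phi), r * sin(phi))
    },
    sickle = {
      el <- cbind(1.9 * base[, 1], base[, 2] / 1.6)
      rb <- 4.8
      cbind((rb - el[, 2]) * sin(el[, 1] / rb),
            rb - (rb - el[, 2]) * cos(el[, 1] / rb))
    })
  if (polygon_area(p) < 0) p <- p[rev(seq_len(nrow(p))), ]
  p <- resample_closed(p, n_vertices)
  if (polygon_area(p) < 0) p <- p[rev(seq_len(nrow(p))), ]
  p <- sweep(p, 2, colMeans(p))
  p <- p * sqrt(area / polygon_area(p))
  p <- sweep(p, 2, colMeans(p))
  structure(p, area = polygon_area(p),
            radius = max(sqrt(rowSums(p^2))),
            half_height = diff(range(p[, 2])) / 2)
}
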