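# Damage models and lesion morphometry: Arrhenius thermal-damage integral,
# threshold-region extraction and the volume/depth/width/symmetry metrics.

#' Arrhenius thermal-damage kinetics
#'
#' First-order injury rate `A exp(-dE / (R T))` with T in kelvin
#' (`A = 2.94e39 1/s`, `dE = 2.596e5 J/mol`). `arrhenius_damage` accumulates
#' the damage integral Omega over a temperature history by trapezoidal
#' quadrature and converts it to a damage probability
#' `P = 100 (1 - exp(-Omega))` percent; Omega = 1 corresponds to 63.2 %.
#'
#' @param T temperature, degC (vectorised).
#' @return `arrhenius_rate`: damage rate, 1/s.
#' @export
arrhenius_rate <- function(T) {
  cst <- .ablatr_const
  cst$arr_A * exp(-cst$arr_dE / (cst$gas_R * (T + 273.15)))
}

#' @rdname arrhenius_rate
#' @param times time points, s (strictly increasing).
#' @param T_history temperatures: a vector (one point) or an
#'   `n_points x length(times)` matrix, degC.
#' @return `arrhenius_damage`: a list with `omega` and `probability` (%).
#' @export
arrhenius_damage <- function(times, T_history) {
  if (is.unsorted(times, strictly = TRUE))
    stop("time vector must be strictly increasing")
  if (is.vector(T_history)) T_history <- matrix(T_history, nrow = 1)
  if (ncol(T_history) != length(times))
    stop("T_history must have one column per time point")
  r <- arrhenius_rate(T_history)
  dt <- diff(times)
  omega <- as.numeric((r[, -ncol(r), drop = FALSE] +
                       r[, -1, drop = FALSE]) %*% dt / 2)
  list(omega = omega, probability = 100 * (1 - exp(-omega)))
}

# Volume fraction of a tetrahedron where a linear nodal field is >= 0, from
# the closed-form simplex truncated-power formula
#   V+/V = sum_{i: d_i > 0} d_i^3 / prod_{j != i} (d_i - d_j).
# D is an M x 4 matrix of nodal values minus the threshold.
.tet_fraction_above <- function(D) {
  M <- nrow(D)
  scale <- pmax(apply(abs(D), 1, max), .Machine$double.xmin)
  # symmetry-breaking perturbation so the divided differences are defined
  D <- D + outer(scale * 1e-9, c(1, 2.1, 3.3, 4.7))
  frac <- numeric(M)
  npos <- rowSums(D > 0)
  full <- npos == 4L; none <- npos == 0L
  frac[full] <- 1
  mix <- which(!full & !none)
  if (length(mix)) {
    Dm <- D[mix, , drop = FALSE]
    f <- numeric(length(mix))
    for (i in 1:4) {
      di <- Dm[, i]
      pos <- di > 0
      if (!any(pos)) next
      pr <- rep(1, length(mix))
      for (j in setdiff(1:4, i)) pr <- pr * (di - Dm[, j])
      f[pos] <- f[pos] + (di^3 / pr)[pos]
    }
    frac[mix] <- pmin(pmax(f, 0), 1)
  }
  frac
}

# Volume fraction above threshold AND on one side of a plane, by a fixed
# barycentric sampling grid (used only for elements straddling the symmetry
# split plane).
.tet_fraction_two <- function(nodes, elems, D, side_fun) {
  nb <- 6L
  gr <- expand.grid(i = 0:nb, j = 0:nb, k = 0:nb)
  gr <- gr[gr$i + gr$j + gr$k <= nb, ]
  l4 <- nb - gr$i - gr$j - gr$k
  B <- cbind(gr$i, gr$j, gr$k, l4) / nb    # barycentric sample points
  # shrink towards the centroid so samples are interior
  B <- B * 0.999 + 0.00025
  out <- numeric(nrow(elems))
  for (r in seq_len(nrow(elems))) {
    P <- B %*% nodes[elems[r, ], , drop = FALSE]
    fv <- as.numeric(B %*% D[r, ])
    out[r] <- mean(fv >= 0 & side_fun(P))
  }
  out
}

#' Extract a lesion region by thresholding a criterion field
#'
#' Flags the tissue (cardiac + skeletal) portion of the mesh where a nodal
#' criterion field reaches its threshold: the maximum-over-time temperature
#' (50 degC isotherm, RFA), the maximum-over-bursts field magnitude
#' (1000 V/cm, PFA) or the Arrhenius damage integral (Omega >= 1). The lesion
#' boundary is located sub-element by linear interpolation along element
#' edges.
#'
#' @param mesh an `ablation_mesh`.
#' @param node_values nodal criterion values.
#' @param threshold criterion threshold (same units as `node_values`).
#' @param elem_values optional element-wise criterion used for element
#'   membership flags (e.g. the element field magnitude).
#' @return an object of class `lesion_region`.
#' @export
extract_lesion_region <- function(mesh, node_values, threshold, elem_values = NULL) {
  if (is.null(node_values)) stop("criterion field missing")
  tissue <- which(mesh$region %in% c("cardiac", "skeletal"))
  ev <- if (is.null(elem_values)) {
    rowMeans(matrix(node_values[mesh$elems], ncol = 4))
  } else elem_values
  structure(list(mesh = mesh, f = node_values, threshold = threshold,
                 tissue_elems = tissue,
                 elements = tissue[ev[tissue] >= threshold]),
            class = "lesion_region")
}

#' Lesion morphometrics
#'
#' Measures the thresholded lesion region: total volume V (mm^3, isosurface
#' clipped), maximum depth D (mm) below the electrode contact plane (the
#' deepest point of the inserted catheter, the convention that reproduces
#' the published depth measurements; the depth below the undeformed
#' endocardial plane z = 0 is also reported), maximum width W (mm, largest lesion caliper parallel to the endocardial plane; for
#' the bipolar configuration the width of the transversal section at the
#' array mid-point is also reported), and the symmetry ratio SR (% of volume
#' upstream / downstream of the plane through the electrode centre normal to
#' the blood-flow direction). For half-domain meshes the mirror image is
#' included automatically.
#'
#' @param region a [extract_lesion_region()] result.
#' @param geometry the `ablation_geometry` (default: from the mesh).
#' @param flow_direction unit vector of the blood-flow direction (+x).
#' @return an object of class `lesion_metrics`: list with `V_mm3`,
#'   `depth_mm` (below the electrode contact plane z = -D_E),
#'   `depth_endocardial_mm` (below the undeformed endocardial plane z = 0),
#'   `width_mm`, `width_transversal_mm`, `extent_x_mm` and `sr`.
#' @export
lesion_metrics <- function(region, geometry = region$mesh$geometry,
                           flow_direction = c(1, 0, 0)) {
  mesh <- region$mesh
  f <- region$f; c0 <- region$threshold
  tis <- region$tissue_elems
  el <- mesh$elems[tis, , drop = FALSE]
  D <- matrix(f[el], ncol = 4) - c0
  keep <- which(rowSums(D > 0) > 0)
  mirror <- isTRUE(mesh$half_domain)
  D_E <- if (!is.null(geometry)) geometry$catheter$D_E else 0
  if (!length(keep)) {
    out <- list(V_mm3 = 0, depth_mm = 0, depth_endocardial_mm = 0,
                width_mm = 0, width_transversal_mm = 0, extent_x_mm = 0,
                sr = c(NA, NA))
    class(out) <- "lesion_metrics"
    return(out)
  }
  el <- el[keep, , drop = FALSE]; D <- D[keep, , drop = FALSE]
  vol <- mesh$vol[tis][keep]
  frac <- .tet_fraction_above(D)
  V <- sum(vol * frac)

  # boundary point set: interior nodes plus edge crossings of the isosurface
  nd <- mesh$nodes
  pts <- nd[unique(as.vector(el))[f[unique(as.vector(el))] >= c0], , drop = FALSE]
  edges <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (eg in edges) {
    a <- D[, eg[1]]; b <- D[, eg[2]]
    cross <- which(a * b < 0)
    if (!length(cross)) next
    t <- a[cross] / (a[cross] - b[cross])
    p1 <- nd[el[cross, eg[1]], , drop = FALSE]
    p2 <- nd[el[cross, eg[2]], , drop = FALSE]
    pts <- rbind(pts, p1 + t * (p2 - p1))
  }
  if (mirror) {
    V <- 2 * V
    pm <- pts; pm[, 2] <- -pm[, 2]
    pts <- rbind(pts, pm)
  }
  depth_endo <- max(0, max(-pts[, 3])) * 1e3
  depth <- max(0, max(-pts[, 3]) - D_E) * 1e3

  xy <- pts[, 1:2, drop = FALSE]
  hull <- unique(grDevices::chull(xy))
  hp <- xy[hull, , drop = FALSE]
  width <- if (nrow(hp) >= 2) sqrt(max(as.numeric(stats::dist(hp))^2)) * 1e3 else 0

  cath <- if (!is.null(geometry)) geometry$catheter else NULL
  x_c <- if (is.null(cath)) 0 else {
    if (cath$type == "monopolar") cath$base[1]
    else cath$base[1] + (cath$electrodes[[1]]$s_lo +
                         cath$electrodes[[length(cath$electrodes)]]$s_hi) / 2 * cath$axis[1]
  }
  # transversal section width at the array mid-plane (bipolar convention)
  slab_w <- 0.75e-3
  near <- abs(pts[, 1] - x_c) <= slab_w
  width_t <- if (any(near)) diff(range(pts[near, 2])) * 1e3 else 0

  # symmetry split: clipped volume on each side of the plane x = x_c
  ctr_x <- rowMeans(matrix(nd[el, 1], ncol = 4))
  xmin <- apply(matrix(nd[el, 1], ncol = 4), 1, min)
  xmax <- apply(matrix(nd[el, 1], ncol = 4), 1, max)
  vup <- sum((vol * frac)[xmax <= x_c])
  straddle <- which(xmin < x_c & xmax > x_c)
  if (length(straddle)) {
    fu <- .tet_fraction_two(nd, el[straddle, , drop = FALSE],
                            D[straddle, , drop = FALSE],
                            side_fun = function(P) P[, 1] <= x_c)
    # renormalise the sampled split to the exact clipped volume of each tet
    ftot <- .tet_fraction_two(nd, el[straddle, , drop = FALSE],
                              D[straddle, , drop = FALSE],
                              side_fun = function(P) rep(TRUE, nrow(P)))
    w <- ifelse(ftot > 0, fu / pmax(ftot, 1e-12), 0)
    vup <- vup + sum(vol[straddle] * frac[straddle] * pmin(w, 1))
  }
  if (mirror) vup <- 2 * vup
  sr <- c(vup, V - vup) / V * 100

  out <- list(V_mm3 = V * 1e9, depth_mm = depth,
              depth_endocardial_mm = depth_endo, width_mm = width,
              width_transversal_mm = width_t,
              extent_x_mm = diff(range(pts[, 1])) * 1e3, sr = sr)
  class(out) <- "lesion_metrics"
  out
}

#' @export
print.lesion_metrics <- function(x, ...) {
  cat(sprintf("Lesion: V = %.2f mm^3, D = %.2f mm, W = %.2f mm (transversal %.2f mm)\n",
              x$V_mm3, x$depth_mm, x$width_mm, x$width_transversal_mm))
  if (!any(is.na(x$sr)))
    cat(sprintf("  symmetry ratio: %.1f %% / %.1f %%\n", x$sr[1], x$sr[2]))
  invisible(x)
}

# Nodal lesion criterion field (V/cm) from an element |E| field, averaged
# only over tissue elements so the conductivity jump at the blood interface
# does not contaminate surface nodes.
lesion_field_vcm <- function(mesh, E_elem) {
  tissue <- which(mesh$region %in% c("cardiac", "skeletal"))
  .nodal_field(mesh, E_elem, subset = tissue) / 100
}
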