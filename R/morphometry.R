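#' Construct a landmark path
#'
#' An ordered sequence of 3D points (mm) tracing the outer edge of the
#' basilar membrane from base to apex, as digitised from a cochlear endocast.
#'
#' @param points numeric matrix or data.frame with columns x, y, z (mm),
#'   ordered base to apex; at least two rows, all coordinates finite,
#'   consecutive points distinct.
#' @param specimen optional specimen identifier.
#' @param side optional, one of `"left"` or `"right"`.
#' @return a `landmark_path`: the coordinate matrix with metadata attributes.
#' @export
landmark_path <- function(points, specimen = NA_character_, side = NA_character_) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3L) stop("landmark path needs 3 coordinate columns", call. = FALSE)
  storage.mode(pts) <- "double"
  if (nrow(pts) < 2L) {
    stop("insufficient landmarks: need at least 2 points, got ", nrow(pts),
         call. = FALSE)
  }
  if (!all(is.finite(pts))) stop("non-finite landmark coordinates", call. = FALSE)
  steps <- diff(pts)
  if (any(rowSums(steps^2) == 0)) {
    stop("consecutive landmark points must be distinct", call. = FALSE)
  }
  if (!is.na(side) && !side %in% c("left", "right")) {
    stop("side must be 'left' or 'right'", call. = FALSE)
  }
  colnames(pts) <- c("x", "y", "z")
  structure(pts, specimen = specimen, side = side,
            class = c("landmark_path", "matrix", "array"))
}

#' Read a landmark path from CSV
#'
#' One row per point, columns `x,y,z` in mm, ordered base to apex.
#'
#' @param path CSV file path.
#' @inheritParams landmark_path
#' @param quiet suppress the point-count message.
#' @return a `landmark_path`.
#' @export
read_landmark_csv <- function(path, specimen = NA_character_,
                              side = NA_character_, quiet = FALSE) {
  d <- read.csv(path)
  if (!all(c("x", "y", "z") %in% names(d))) {
    stop("landmark CSV must have columns x, y, z", call. = FALSE)
  }
  if (!quiet) message("read ", nrow(d), " landmark points")
  landmark_path(d[, c("x", "y", "z")], specimen = specimen, side = side)
}

#' Basilar membrane length as a polyline arc length
#'
#' Sums the Euclidean distances between consecutive landmark points, the
#' chord-length estimate of membrane arc length. Chords underestimate a
#' smooth curve, so the estimate increases as the landmark density grows.
#'
#' @param path a `landmark_path` (or an n x 3 coordinate matrix).
#' @return total length in mm.
#' @export
polyline_length <- function(path) {
  pts <- if (inherits(path, "landmark_path")) unclass(path) else
    unclass(landmark_path(path))
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Count cochlear spiral turns
#'
#' The primary estimator is the cumulative winding angle of the path,
#' projected onto the plane orthogonal to `apex_axis`, about the spiral
#' centre, divided by 360 degrees. The centre is estimated by scoring
#' candidate centres (path end points, a least-squares circle fit, the
#' centroid) on how smoothly radius varies with winding angle. A secondary
#' line-crossing estimate counts crossings of the full line through
#' `start_point` and the centre (the manual convention of counting how
#' often the duct crosses a line from the round window to the apex) divided
#' by two. Counts are reported to the nearest quarter turn.
#'
#' @param path a `landmark_path`.
#' @param apex_axis 3D direction of the modiolar (base-to-apex) axis used
#'   for the apical-view projection; default `c(0, 0, 1)`.
#' @param start_point 3D point anchoring the crossing line, default the
#'   first landmark (the round-window end).
#' @return an object of class `turn_count`: list with `raw_turns`,
#'   `quarter_rounded`, `crossing_turns`, and the estimated `centre`.
#' @export
count_turns <- function(path, apex_axis = c(0, 0, 1), start_point = NULL) {
  pts <- if (inherits(path, "landmark_path")) unclass(path) else
    unclass(landmark_path(path))
  if (is.null(start_point)) start_point <- pts[1, ]
  axis <- apex_axis / sqrt(sum(apex_axis^2))
  basis <- .plane_basis(axis)
  p2 <- pts %*% basis                       # n x 2 projected path
  s2 <- drop(rbind(start_point) %*% basis)
  ctr <- matrix(colMeans(p2), ncol = 2)
  spread <- sweep(p2, 2, colMeans(p2))
  sv <- svd(spread, nu = 0, nv = 0)$d
  if (sv[1] == 0 || sv[2] / sv[1] < 1e-8) {
    stop("degenerate projection: landmarks are collinear in the chosen plane",
         call. = FALSE)
  }
  centre <- .spiral_centre(p2)
  raw <- .winding_turns(p2, centre)
  crossing <- .crossing_turns(p2, centre, s2)
  qr_ <- round(raw / 0.25) * 0.25
  structure(list(raw_turns = raw, quarter_rounded = qr_,
                 crossing_turns = crossing, centre = centre),
            class = "turn_count")
}

#' @export
print.turn_count <- function(x, ...) {
  cat(sprintf("Cochlear turns: %.2f raw, %.2f to the nearest quarter (line-crossing check: %.2f)\n",
              x$raw_turns, x$quarter_rounded, x$crossing_turns))
  invisible(x)
}

# orthonormal basis of the plane orthogonal to a unit axis
.plane_basis <- function(axis) {
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  cbind(u, v)
}

# Choose the spiral centre among candidates by the smoothness of radius as
# a function of winding angle: seen from the true centre, r(psi) of an
# Archimedean spiral or circular arc is closely quadratic and that of a
# tapered (logarithmic) spiral is log-linear; seen from a wrong centre both
# oscillate. The score is the lack of fit (1 - R^2) of a quadratic in psi,
# taken in whichever of r or log r fits better.
.spiral_centre <- function(p2) {
  n <- nrow(p2)
  cand <- rbind(p2[1, ], p2[n, ], .circle_fit(p2), colMeans(p2))
  scale2 <- mean(rowSums(sweep(p2, 2, colMeans(p2))^2))
  score_fn <- function(c0) {
    d <- sweep(p2, 2, c0)
    r <- sqrt(rowSums(d^2))
    keep <- r > 1e-9 * sqrt(scale2)
    if (sum(keep) < 5) return(Inf)
    psi <- .unwrap(atan2(d[keep, 2], d[keep, 1]))
    Xq <- cbind(1, psi, psi^2)
    lack <- function(y) {
      tss <- sum((y - mean(y))^2)
      if (tss <= 1e-18 * max(1, mean(y)^2)) return(0)
      sum(lm.fit(Xq, y)$residuals^2) / tss
    }
    min(lack(r[keep]), lack(log(r[keep])))
  }
  # the min() of the two lack-of-fit surfaces is kinked, so refine each
  # metric separately from every candidate and keep the overall best
  single <- function(c0, use_log) {
    d <- sweep(p2, 2, c0)
    r <- sqrt(rowSums(d^2))
    keep <- r > 1e-9 * sqrt(scale2)
    if (sum(keep) < 5) return(Inf)
    psi <- .unwrap(atan2(d[keep, 2], d[keep, 1]))
    y <- if (use_log) log(r[keep]) else r[keep]
    tss <- sum((y - mean(y))^2)
    if (tss <= 1e-18 * max(1, mean(y)^2)) return(0)
    sum(lm.fit(cbind(1, psi, psi^2), y)$residuals^2) / tss
  }
  best <- cand[1, ]
  best_score <- Inf
  step <- 0.1 * sqrt(scale2)
  for (i in seq_len(nrow(cand))) {
    for (use_log in c(FALSE, TRUE)) {
      ref <- tryCatch(
        stats::optim(cand[i, ], single, use_log = use_log,
                     method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-12,
                                    parscale = c(step, step))),
        error = function(e) NULL)
      pts <- rbind(cand[i, ], if (!is.null(ref)) ref$par)
      for (j in seq_len(nrow(pts))) {
        s <- score_fn(pts[j, ])
        if (is.finite(s) && s < best_score) {
          best_score <- s
          best <- pts[j, ]
        }
      }
    }
  }
  best
}

# algebraic (Kasa) least-squares circle fit
.circle_fit <- function(p2) {
  A <- cbind(2 * p2[, 1], 2 * p2[, 2], 1)
  b <- rowSums(p2^2)
  z <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(z)) colMeans(p2) else z[1:2]
}

.unwrap <- function(angles) {
  d <- diff(angles)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(angles[1], d))
}

.winding_turns <- function(p2, centre) {
  d <- sweep(p2, 2, centre)
  r <- sqrt(rowSums(d^2))
  keep <- r > 1e-9 * max(r)
  ang <- .unwrap(atan2(d[keep, 2], d[keep, 1]))
  abs(ang[length(ang)] - ang[1]) / (2 * pi)
}

.crossing_turns <- function(p2, centre, start2) {
  dir <- start2 - centre
  if (sqrt(sum(dir^2)) < 1e-9 * max(sqrt(rowSums(sweep(p2, 2, centre)^2)))) {
    # start point coincides with the centre: anchor the line at the point
    # farthest from the centre instead
    r <- rowSums(sweep(p2, 2, centre)^2)
    dir <- p2[which.max(r), ] - centre
  }
  dir <- dir / sqrt(sum(dir^2))
  nrm <- c(-dir[2], dir[1])
  d <- sweep(p2, 2, centre)
  side <- drop(d %*% nrm)
  eps <- 0.01 * max(sqrt(rowSums(d^2)))
  nz <- abs(side) > eps
  crossings <- sum(diff(sign(side[nz])) != 0)
  # the path starts (and for whole half-turns ends) on the line itself;
  # such boundary touches are half crossings
  touches <- (!nz[1]) + (!nz[length(nz)])
  (crossings + 0.5 * touches) / 2
}

#' Relative basilar membrane length
#'
#' Membrane length divided by body mass to the power `exponent` (cube root
#' by default), removing isometric size scaling; units mm / g^exponent.
#'
#' @param length membrane length in mm (> 0).
#' @param mass body mass in g (> 0).
#' @param exponent scaling exponent; `1/3` by default, `0.33` accepted.
#' @return relative length, vectorised over inputs.
#' @export
relative_membrane_length <- function(length, mass, exponent = 1/3) {
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("membrane length must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("mass must be finite and positive", call. = FALSE)
  }
  length / mass^exponent
}

#' Absolute membrane length from a relative value
#'
#' Inverse of [relative_membrane_length()]: multiplies a mass-scaled
#' relative length (mm / g^exponent) back to absolute mm at a given mass.
#'
#' @param relative relative membrane length (> 0).
#' @inheritParams relative_membrane_length
#' @return absolute length in mm.
#' @export
absolute_membrane_length <- function(relative, mass, exponent = 1/3) {
  if (any(!is.finite(relative)) || any(relative <= 0)) {
    stop("relative length must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("mass must be finite and positive", call. = FALSE)
  }
  relative * mass^exponent
}
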