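#' Eye/beak head calibration
#'
#' Positions of the left eye, right eye and beak tip expressed in the
#' rigid-body frame of the four head markers (the "template" frame), as
#' produced by a multi-camera calibration session. The marker template
#' holds the four head-marker positions in the same frame.
#'
#' `head_up` is the head-dorsal direction in the template frame, used to
#' pick the plane in which the forward axis is raised above the beak
#' line and to orient the head Z axis. If omitted it defaults to the
#' eye-axis/beak normal pointing dorsally, i.e. the normal closest to
#' world-up for a level head at calibration; recording it here keeps the
#' head frame independent of the capture rig.
#'
#' @param left_eye,right_eye,beak_tip numeric length-3 points (m),
#'   template frame.
#' @param template 4 x 3 matrix of head-marker positions (m), template
#'   frame; must have rank 3 after centering.
#' @param head_up optional numeric length-3 dorsal direction.
#' @return an object of class `head_calibration`.
#' @export
head_calibration <- function(left_eye, right_eye, beak_tip, template,
                             head_up = NULL) {
  left_eye <- as.numeric(left_eye); right_eye <- as.numeric(right_eye)
  beak_tip <- as.numeric(beak_tip)
  template <- as.matrix(template)
  stopifnot(length(left_eye) == 3L, length(right_eye) == 3L,
            length(beak_tip) == 3L, all(dim(template) == c(4L, 3L)),
            all(is.finite(template)))
  if (vnorm(right_eye - left_eye) < 1e-6)
    stop("degenerate calibration: eyes coincide")
  origin <- (left_eye + right_eye) / 2
  e <- right_eye - left_eye
  b <- beak_tip - origin
  if (vnorm(b) < 1e-6 ||
      vec_angle(e, b) < deg2rad(2) || vec_angle(e, b) > pi - deg2rad(2))
    stop("degenerate calibration: beak tip collinear with the eye axis")
  centered <- sweep(template, 2, colMeans(template))
  if (qr(centered)$rank < 3L)
    stop("degenerate calibration: marker template is rank deficient")
  if (is.null(head_up)) head_up <- normalize3(cross3(e, b))
  else head_up <- normalize3(as.numeric(head_up))
  structure(list(left_eye = left_eye, right_eye = right_eye,
                 beak_tip = beak_tip, template = template,
                 head_up = head_up),
            class = "head_calibration")
}

#' Read / write an eye-beak calibration table
#'
#' Long CSV: columns `bird, point, x, y, z` with points `left_eye`,
#' `right_eye`, `beak_tip`, `head_up`, `marker1..marker4`, coordinates in
#' the template frame (m).
#'
#' @param path file path.
#' @return [read_calibration_csv()] returns a named list of
#'   [head_calibration()] objects (one per bird).
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird", "point", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("calibration file must have columns ", paste(need, collapse = ", "))
  out <- list()
  for (b in unique(df$bird)) {
    d <- df[df$bird == b, ]
    pt <- function(lbl) {
      r <- d[d$point == lbl, c("x", "y", "z")]
      if (nrow(r) != 1L) stop("bird ", b, ": need exactly one '", lbl, "' row")
      as.numeric(r)
    }
    template <- t(vapply(paste0("marker", 1:4), pt, numeric(3)))
    up <- if ("head_up" %in% d$point) pt("head_up") else NULL
    out[[b]] <- head_calibration(pt("left_eye"), pt("right_eye"),
                                 pt("beak_tip"), template, up)
  }
  out
}

#' @rdname read_calibration_csv
#' @param calibs named list of `head_calibration` objects.
#' @export
write_calibration_csv <- function(calibs, path) {
  rows <- list()
  for (b in names(calibs)) {
    cal <- calibs[[b]]
    pts <- rbind(left_eye = cal$left_eye, right_eye = cal$right_eye,
                 beak_tip = cal$beak_tip, head_up = cal$head_up,
                 cal$template)
    rownames(pts)[5:8] <- paste0("marker", 1:4)
    rows[[b]] <- data.frame(bird = b, point = rownames(pts),
                            x = pts[, 1], y = pts[, 2], z = pts[, 3],
                            row.names = NULL)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Least-squares rigid alignment (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum_i || R template_i + t - observed_i ||^2`. Reflections are never
#' returned; if the best orthogonal transform is a reflection the
#' nearest proper rotation is used. Markers with any non-finite
#' coordinate are dropped; at least three are required.
#'
#' @param observed k x 3 matrix of observed marker positions (world, m);
#'   rows with `NA` are ignored.
#' @param template k x 3 matrix of template positions (same row order).
#' @return list with `R` (3 x 3, `det = +1`), `t` (length 3), `rmsd`
#'   (m), and `n_used`; or `NULL` when fewer than 3 markers are valid.
#' @export
rigid_align <- function(observed, template) {
  observed <- as.matrix(observed); template <- as.matrix(template)
  stopifnot(ncol(observed) == 3L, ncol(template) == 3L,
            nrow(observed) == nrow(template))
  ok <- stats::complete.cases(observed) & stats::complete.cases(template)
  if (sum(ok) < 3L) return(NULL)
  A <- template[ok, , drop = FALSE]
  B <- observed[ok, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - as.numeric(R %*% ca)
  fitted <- sweep(A %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(R = R, t = t, rmsd = rmsd, n_used = sum(ok))
}

#' Construct the head-local coordinate system
#'
#' Origin is the midpoint of the two eyes. The forward (+Y) axis points
#' to the horizon, defined as `horizon_offset_deg` (30 by default) above
#' the origin-to-beak line in elevation, raised within the plane spanned
#' by the beak direction and the head-up direction. +X points toward the
#' right eye (orthogonalized against Y) and Z = X x Y (head-up);
#' the frame is right-handed. In the resulting frame the beak direction
#' has elevation `-horizon_offset_deg` and azimuth 0, and the eyes lie
#' at elevation 0 with azimuth components of opposite sign.
#'
#' @param left_eye,right_eye,beak_tip length-3 points in any common
#'   frame.
#' @param head_up optional dorsal direction in the same frame (defaults
#'   to the eye-axis/beak normal).
#' @param horizon_offset_deg elevation of the horizon above the beak
#'   line, degrees.
#' @return list with `origin` (length 3) and `R` (3 x 3 rotation whose
#'   columns are the head X, Y, Z axes in the input frame).
#' @export
build_head_frame <- function(left_eye, right_eye, beak_tip,
                             head_up = NULL, horizon_offset_deg = 30) {
  origin <- (left_eye + right_eye) / 2
  e <- right_eye - left_eye
  b <- beak_tip - origin
  if (vnorm(e) < 1e-9 || vnorm(b) < 1e-9)
    stop("degenerate head geometry: coincident calibration points")
  ang_eb <- vec_angle(e, b)
  if (ang_eb < deg2rad(2) || ang_eb > pi - deg2rad(2))
    stop("degenerate head geometry: beak tip collinear with the eye axis")
  bh <- normalize3(b)
  up <- if (is.null(head_up)) cross3(normalize3(e), bh) else head_up
  u <- up - sum(up * bh) * bh
  if (vnorm(u) < 1e-9)
    stop("degenerate head geometry: head-up parallel to the beak line")
  u <- normalize3(u)
  th <- deg2rad(horizon_offset_deg)
  Y <- cos(th) * bh + sin(th) * u
  X <- e - sum(e * Y) * Y
  if (vnorm(X) < 1e-9)
    stop("degenerate head geometry: eye axis parallel to the forward axis")
  X <- normalize3(X)
  Z <- cross3(X, Y)
  list(origin = origin, R = cbind(X, Y, Z, deparse.level = 0))
}

#' Head-pose series
#'
#' Per-frame head origin (eye midpoint, world) and world-from-head
#' rotation per bird, with validity flags and alignment residuals.
#'
#' @param frame_rate Hz.
#' @param frames integer frame indices.
#' @param birds named list; per bird a list with `origin` (n x 3), `R`
#'   (3 x 3 x n), `valid` (logical n), `rmsd` (numeric n).
#' @return object of class `head_pose_series`.
#' @export
head_pose_series <- function(frame_rate, frames, birds) {
  structure(list(frame_rate = frame_rate, frames = as.integer(frames),
                 birds = birds),
            class = "head_pose_series")
}

#' @export
print.head_pose_series <- function(x, ...) {
  nv <- vapply(x$birds, function(b) sum(b$valid), integer(1))
  cat("Head-pose series:", length(x$birds), "birds,",
      length(x$frames), "frames @", x$frame_rate, "Hz\n")
  cat("  valid pose frames:",
      paste0(names(x$birds), "=", nv, collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct head poses from marker trajectories
#'
#' For every frame with at least three valid head markers, rigidly
#' aligns the calibration template onto the observed markers
#' ([rigid_align()]), maps the calibrated eye/beak/head-up points into
#' the world frame, and builds the head-local coordinate system
#' ([build_head_frame()]). Frames with fewer than three valid markers
#' are marked invalid, never guessed.
#'
#' @param markers a [marker_series()].
#' @param calibs named list of [head_calibration()]s covering every bird
#'   in `markers`.
#' @param config a [scene_config()].
#' @return a [head_pose_series()].
#' @export
reconstruct_head_poses <- function(markers, calibs, config) {
  stopifnot(inherits(markers, "marker_series"))
  n <- n_frames(markers)
  birds <- list()
  for (b in bird_ids(markers)) {
    cal <- calibs[[b]]
    if (is.null(cal)) stop("no calibration for bird ", b)
    head <- markers$birds[[b]]$head
    origin <- matrix(NA_real_, n, 3L)
    Rarr <- array(NA_real_, c(3L, 3L, n))
    valid <- logical(n)
    rmsd <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      al <- rigid_align(head[i, , ], cal$template)
      if (is.null(al)) next
      w <- function(p) as.numeric(al$R %*% p + al$t)
      fr <- build_head_frame(w(cal$left_eye), w(cal$right_eye),
                             w(cal$beak_tip),
                             head_up = as.numeric(al$R %*% cal$head_up))
      origin[i, ] <- fr$origin
      Rarr[, , i] <- fr$R
      valid[i] <- TRUE
      rmsd[i] <- al$rmsd
    }
    birds[[b]] <- list(origin = origin, R = Rarr, valid = valid, rmsd = rmsd)
  }
  head_pose_series(markers$frame_rate, markers$frames, birds)
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end) of
# 1-based indices.
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Moving average with shrinking windows at run edges (zero phase).
moving_average <- function(x, w) {
  if (w <= 1L || length(x) < 2L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Interpolate short gaps and smooth a head-pose series
#'
#' Gaps up to `max_gap_frames` are filled (positions linearly, rotations
#' by geodesic interpolation); longer gaps remain invalid. A zero-phase
#' moving-average low-pass (window `window_frames`, shrinking at run
#' edges) is then applied to positions and to orientations in the
#' rotation-vector domain, and rotations are re-orthonormalized.
#'
#' @param poses a [head_pose_series()].
#' @param config a [scene_config()]; `config$smoothing` supplies
#'   `max_gap_frames` and `window_frames`.
#' @return a smoothed [head_pose_series()].
#' @export
smooth_poses <- function(poses, config) {
  max_gap <- as.integer(config$smoothing$max_gap_frames)
  w <- as.integer(config$smoothing$window_frames)
  out <- poses
  for (b in names(poses$birds)) {
    pb <- poses$birds[[b]]
    valid <- pb$valid
    runs <- true_runs(valid)
    # fill gaps between consecutive valid runs
    if (nrow(runs) > 1L) {
      for (k in seq_len(nrow(runs) - 1L)) {
        g0 <- runs$end[k]; g1 <- runs$start[k + 1L]
        gap <- g1 - g0 - 1L
        if (gap >= 1L && gap <= max_gap &&
            poses$frames[g1] - poses$frames[g0] == g1 - g0) {
          for (i in seq_len(gap)) {
            t <- i / (gap + 1)
            pb$origin[g0 + i, ] <-
              (1 - t) * pb$origin[g0, ] + t * pb$origin[g1, ]
            pb$R[, , g0 + i] <- rot_slerp(pb$R[, , g0], pb$R[, , g1], t)
            pb$valid[g0 + i] <- TRUE
          }
        }
      }
    }
    # low-pass within each (now extended) valid run
    runs <- true_runs(pb$valid)
    for (k in seq_len(nrow(runs))) {
      idx <- runs$start[k]:runs$end[k]
      if (length(idx) < 2L) next
      for (j in 1:3)
        pb$origin[idx, j] <- moving_average(pb$origin[idx, j], w)
      if (w > 1L) {
        V <- t(vapply(idx, function(i) rot_to_vec(pb$R[, , i]), numeric(3)))
        # keep consecutive rotation vectors on the same branch
        for (i in seq_len(nrow(V))[-1]) {
          ang <- vnorm(V[i, ])
          if (ang > 1e-9) {
            alt <- V[i, ] * (1 - 2 * pi / ang)
            if (vnorm(alt - V[i - 1L, ]) < vnorm(V[i, ] - V[i - 1L, ]))
              V[i, ] <- alt
          }
        }
        for (j in 1:3) V[, j] <- moving_average(V[, j], w)
        for (i in seq_along(idx))
          pb$R[, , idx[i]] <- orthonormalize_rot(vec_to_rot(V[i, ]))
      }
    }
    out$birds[[b]] <- pb
  }
  out
}

#' Flag head-saccade frames
#'
#' A frame is flagged when the geodesic angular speed from the previous
#' valid consecutive frame exceeds the threshold. The first frame of
#' every valid run is never flagged (no preceding pose to compare with).
#' Avian visual processing is suppressed during rapid head rotations, so
#' flagged frames are excluded from looking.
#'
#' @param poses a [head_pose_series()].
#' @param threshold_deg_s angular-speed threshold in deg/s (> 0).
#' @return named list of logical vectors (one per bird), `NA` on
#'   invalid-pose frames.
#' @export
detect_saccades <- function(poses, threshold_deg_s) {
  stopifnot(threshold_deg_s > 0)
  lapply(poses$birds, function(pb) {
    n <- length(pb$valid)
    m <- rep(NA, n)
    m[pb$valid] <- FALSE
    if (n < 2L) return(m)
    # tr(R_{i-1}' R_i) = elementwise sum of products
    tr <- colSums(matrix(pb$R[, , 1:(n - 1L)] * pb$R[, , 2:n], 9L))
    ang <- acos(pmax(-1, pmin(1, (tr - 1) / 2)))
    speed <- rad2deg(ang) * poses$frame_rate
    consec <- pb$valid[-1L] & pb$valid[-n] &
      diff(poses$frames) == 1L
    idx <- which(consec) + 1L
    m[idx] <- speed[idx - 1L] > threshold_deg_s
    m
  })
}

#' Flag grooming frames
#'
#' Reference heuristic: a frame is flagged when the head pitch (elevation
#' of the forward axis) is below `pitch_threshold_deg` and the eye
#' midpoint is within `dist_threshold_m` of the backpack centroid, both
#' sustained for at least `min_ms`. A bird attending to its own plumage
#' is not attending to the environment, so these frames are excluded from
#' looking. Alternatively an externally produced mask (e.g. from a
#' dedicated behavioral classifier) is passed through verbatim.
#'
#' @param poses a [head_pose_series()].
#' @param markers the [marker_series()] holding backpack tracks.
#' @param config a [scene_config()]; `config$grooming` supplies the
#'   thresholds.
#' @param external optional named list of logical vectors to pass
#'   through unchanged.
#' @return named list of logical vectors, `NA` on invalid-pose frames.
#' @export
detect_grooming <- function(poses, markers, config, external = NULL) {
  if (!is.null(external)) return(external)
  g <- config$grooming
  min_frames <- max(1L, ceiling(g$min_ms / 1000 * poses$frame_rate))
  out <- list()
  for (b in names(poses$birds)) {
    pb <- poses$birds[[b]]
    n <- length(pb$valid)
    bp <- markers$birds[[b]]$backpack
    m <- rep(NA, n)
    m[pb$valid] <- FALSE
    cond <- logical(n)
    if (dim(bp)[2] > 0L && n > 0L) {
      pitch <- rad2deg(asin(pmax(-1, pmin(1, pb$R[3, 2, ]))))
      ctr <- apply(bp, c(1, 3), mean, na.rm = TRUE)  # n x 3 centroid
      dist <- sqrt(rowSums((ctr - pb$origin)^2))
      cond <- pb$valid & is.finite(pitch) & is.finite(dist) &
        pitch < g$pitch_threshold_deg & dist < g$dist_threshold_m
    }
    runs <- true_runs(cond)
    runs <- runs[runs$end - runs$start + 1L >= min_frames, , drop = FALSE]
    for (k in seq_len(nrow(runs))) m[runs$start[k]:runs$end[k]] <- TRUE
    out[[b]] <- m
  }
  out
}
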