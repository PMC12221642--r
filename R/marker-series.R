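#' Marker time series
#'
#' Raw per-frame 3D marker coordinates for a flock, world frame, meters.
#' Each bird carries exactly four head markers and (optionally) backpack
#' markers. Missing samples are `NA` and carried as an explicit validity
#' mask; they are never zeros.
#'
#' @param frame_rate capture rate in Hz.
#' @param frames integer vector of 0-based frame indices (monotone).
#' @param birds named list; each element a list with `head` (an
#'   `n x 4 x 3` array) and `backpack` (an `n x k x 3` array, possibly
#'   `k = 0`).
#' @return an object of class `marker_series`.
#' @export
marker_series <- function(frame_rate, frames, birds) {
  stopifnot(frame_rate > 0, is.numeric(frames),
            !is.null(names(birds)), all(nzchar(names(birds))))
  frames <- as.integer(frames)
  if (length(frames) > 1L && any(diff(frames) <= 0L))
    stop("frame index must be strictly increasing")
  n <- length(frames)
  for (b in names(birds)) {
    h <- birds[[b]]$head
    if (!is.array(h) || length(dim(h)) != 3L || dim(h)[1] != n ||
        dim(h)[2] != 4L || dim(h)[3] != 3L)
      stop("bird ", b, ": head markers must be an n x 4 x 3 array")
    if (is.null(birds[[b]]$backpack))
      birds[[b]]$backpack <- array(NA_real_, c(n, 0L, 3L))
  }
  structure(list(frame_rate = frame_rate, frames = frames, birds = birds),
            class = "marker_series")
}

#' @export
print.marker_series <- function(x, ...) {
  cat("Marker time series:", length(x$birds), "birds,",
      length(x$frames), "frames @", x$frame_rate, "Hz\n")
  nv <- vapply(x$birds, function(b)
    sum(stats::complete.cases(matrix(b$head, ncol = 12L))), integer(1))
  cat("  fully tracked head frames per bird:",
      paste0(names(x$birds), "=", nv, collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames and bird identifiers of a marker series
#' @param x a `marker_series`.
#' @return integer count / character vector of bird ids.
#' @export
n_frames <- function(x) length(x$frames)

#' @rdname n_frames
#' @export
bird_ids <- function(x) names(x$birds)

# Per-frame marker validity (all three coordinates finite).
marker_valid <- function(track3) {
  apply(is.finite(track3), c(1, 2), all)
}

marker_labels <- function(n_back) {
  c(paste0("head", 1:4), if (n_back > 0) paste0("back", seq_len(n_back)))
}

#' Read motion-capture marker coordinates from CSV
#'
#' The expected dialect is a plain header `frame` followed by columns
#' `<bird>_<marker>_<axis>` with axis in x/y/z, coordinates in meters,
#' world frame, Z up. Head markers are labeled `head1..head4`, backpack
#' markers `back1..backK`. Empty cells are missing samples and become
#' invalid-masked `NA`s.
#'
#' @param path CSV file path.
#' @param config a [scene_config()] supplying the frame rate.
#' @return a [marker_series()].
#' @export
read_mocap_csv <- function(path, config) {
  stopifnot(inherits(config, "scene_config"))
  if (!file.exists(path)) stop("mocap file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L || names(df)[1] != "frame")
    stop("malformed mocap header: first column must be 'frame'")
  frames <- suppressWarnings(as.integer(df$frame))
  if (anyNA(frames)) stop("non-integer values in frame column")
  if (length(frames) > 1L && any(diff(frames) <= 0L))
    stop("frame column is not strictly increasing")

  cols <- names(df)[-1]
  parts <- strsplit(cols, "_")
  for (i in seq_along(cols)) {
    p <- parts[[i]]
    if (length(p) < 3L || !(p[length(p)] %in% c("x", "y", "z")))
      stop("malformed mocap header: cannot parse column '", cols[i], "'")
  }
  axis <- vapply(parts, function(p) p[length(p)], character(1))
  marker <- vapply(parts, function(p) p[length(p) - 1L], character(1))
  bird <- vapply(parts, function(p)
    paste(p[seq_len(length(p) - 2L)], collapse = "_"), character(1))
  bad <- !grepl("^(head[1-4]|back[0-9]+)$", marker)
  if (any(bad))
    stop("malformed mocap header: unknown marker label in column '",
         cols[which(bad)[1]], "'")

  n <- length(frames)
  num <- vapply(df[-1], function(v) {
    v[!nzchar(v)] <- NA_character_
    as.numeric(v)
  }, numeric(n))
  if (n == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, cols))

  birds <- list()
  for (b in unique(bird)) {
    sel <- bird == b
    mk <- unique(marker[sel])
    heads <- sort(mk[grepl("^head", mk)])
    if (!identical(heads, paste0("head", 1:4)))
      stop("bird ", b, ": expected head markers head1..head4, found ",
           paste(heads, collapse = ", "))
    backs <- sort(mk[grepl("^back", mk)])
    get_track <- function(labels) {
      a <- array(NA_real_, c(n, length(labels), 3L))
      for (j in seq_along(labels)) {
        for (k in 1:3) {
          cn <- paste(b, labels[j], c("x", "y", "z")[k], sep = "_")
          if (!cn %in% cols)
            stop("malformed mocap header: missing column '", cn, "'")
          a[, j, k] <- num[, cn]
        }
      }
      a
    }
    birds[[b]] <- list(head = get_track(heads),
                       backpack = if (length(backs)) get_track(backs)
                                  else array(NA_real_, c(n, 0L, 3L)))
  }
  marker_series(config$frame_rate, frames, birds)
}

#' Write motion-capture marker coordinates to CSV
#'
#' Inverse of [read_mocap_csv()]; numeric values are printed with full
#' precision (17 significant digits) so a read/write cycle reproduces the
#' series exactly. Missing samples are written as empty fields.
#'
#' @param series a [marker_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mocap_csv <- function(series, path) {
  stopifnot(inherits(series, "marker_series"))
  cols <- list(frame = as.character(series$frames))
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.17g", v), "")
  for (b in names(series$birds)) {
    tr <- series$birds[[b]]
    put <- function(a, labels) {
      for (j in seq_along(labels)) for (k in 1:3) {
        cn <- paste(b, labels[j], c("x", "y", "z")[k], sep = "_")
        cols[[cn]] <<- fmt(a[, j, k])
      }
    }
    put(tr$head, paste0("head", 1:4))
    nb <- dim(tr$backpack)[2]
    if (nb > 0) put(tr$backpack, paste0("back", seq_len(nb)))
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
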