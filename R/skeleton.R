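#' Construct a skeleton clip
#'
#' A skeleton clip is a short (nominally 3 s at 30 Hz) stream of 20-joint 3D
#' skeleton frames, the universal input of every risk module. Coordinates are
#' in meters in a right-handed camera frame with y approximately up.
#'
#' @param frames A data frame in long format with columns `frame` (integer),
#'   `t` (seconds), `joint` (one of [joint_names()]), `x`, `y`, `z` (meters)
#'   and `tracked` (logical). Every frame must carry all 20 joints; untracked
#'   joints keep a row (their coordinates are sentinels and are forward-filled
#'   from the most recent tracked frame when consumed).
#' @param frame_rate Frames per second (default 30).
#' @param p_gt Optional ground-truth fall risk in \[0, 1\] for the whole clip.
#' @param behavior Optional behavior tag (see [behavior_types()]).
#' @param clip_id Optional identifier.
#' @param depth_profile Optional depth profile tibble with columns `frame`,
#'   `upper_mean_depth`, `lower_mean_depth` (meters), used for occlusion
#'   detection.
#'
#' @return An object of class `skeleton_clip`.
#' @export
skeleton_clip <- function(frames, frame_rate = 30, p_gt = NULL,
                          behavior = NULL, clip_id = NULL,
                          depth_profile = NULL) {
  frames <- tibble::as_tibble(frames)
  needed <- c("frame", "joint", "x", "y", "z", "tracked")
  missing_cols <- setdiff(needed, names(frames))
  if (length(missing_cols) > 0) {
    stop("frames is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"t" %in% names(frames)) {
    frames$t <- (frames$frame - min(frames$frame)) / frame_rate
  }
  frames <- dplyr::arrange(frames, .data$frame,
                           match(.data$joint, joint_names()))
  fr <- unique(frames$frame)
  if (length(fr) < 2) stop("a skeleton clip needs at least 2 frames")
  if (nrow(frames) != length(fr) * 20 ||
      !all(frames$joint %in% joint_names())) {
    stop("every frame must carry exactly the 20 named joints")
  }
  bad <- frames$tracked & !(is.finite(frames$x) & is.finite(frames$y) &
                              is.finite(frames$z))
  if (any(bad)) stop("tracked joints must have finite coordinates")
  structure(
    list(frames = frames, frame_rate = frame_rate, p_gt = p_gt,
         behavior = behavior, clip_id = clip_id,
         depth_profile = depth_profile),
    class = "skeleton_clip"
  )
}

#' @export
print.skeleton_clip <- function(x, ...) {
  nf <- length(unique(x$frames$frame))
  cat(sprintf("<skeleton_clip> %d frames @ %g Hz (%.2f s)",
              nf, x$frame_rate, nf / x$frame_rate))
  if (!is.null(x$behavior)) cat(" behavior:", x$behavior)
  if (!is.null(x$p_gt)) cat(sprintf(" p_gt: %.2f", x$p_gt))
  cat("\n")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble skeleton_clip
#' @export
as_tibble.skeleton_clip <- function(x, ...) x$frames

n_frames <- function(clip) length(unique(clip$frames$frame))

# Dense array view of a clip: pos is n x 20 x 3, tracked is n x 20 logical,
# both ordered by joint_names(). The workhorse for all vectorized kinematics.
clip_arrays <- function(clip) {
  jn <- joint_names()
  fr <- clip$frames
  n <- nrow(fr) / 20
  # arrange() in the constructor guarantees frame-major, joint-minor order
  pos <- array(NA_real_, dim = c(n, 20, 3),
               dimnames = list(NULL, jn, c("x", "y", "z")))
  m <- matrix(fr$x, nrow = 20)
  pos[, , 1] <- t(m)
  pos[, , 2] <- t(matrix(fr$y, nrow = 20))
  pos[, , 3] <- t(matrix(fr$z, nrow = 20))
  tracked <- t(matrix(fr$tracked, nrow = 20))
  colnames(tracked) <- jn
  list(pos = pos, tracked = tracked,
       t = fr$t[seq(1, nrow(fr), by = 20)],
       frame = fr$frame[seq(1, nrow(fr), by = 20)])
}

# Forward-fill untracked joints from the most recent tracked frame within the
# clip (on-line behavior: never fill backwards, never across clips). Returns
# the filled positions and a logical matrix of joints still missing (untracked
# with no history).
fill_untracked <- function(arr) {
  pos <- arr$pos
  tracked <- arr$tracked
  missing <- !tracked
  n <- nrow(tracked)
  for (j in seq_len(ncol(tracked))) {
    tj <- tracked[, j]
    if (all(tj)) next
    # index of last tracked frame at or before each frame (0 = none)
    last <- cummax(ifelse(tj, seq_len(n), 0L))
    has <- last > 0L
    fillable <- !tj & has
    if (any(fillable)) {
      pos[fillable, j, ] <- pos[last[fillable], j, , drop = FALSE]
      missing[fillable, j] <- FALSE
    }
  }
  list(pos = pos, missing = missing)
}

coerce_frame <- function(frame) {
  frame <- tibble::as_tibble(frame)
  if (!"tracked" %in% names(frame)) frame$tracked <- TRUE
  if (nrow(frame) != 20 || !all(joint_names() %in% frame$joint)) {
    stop("a skeleton frame needs exactly the 20 named joints")
  }
  frame[match(joint_names(), frame$joint), ]
}

#' Sixty-dimensional frame feature vector
#'
#' Concatenates the (x, y, z) coordinates of the 20 joints in the fixed
#' [joint_names()] order into the 60-vector consumed by the posture
#' classifiers. The order is set by the joint enumeration, never by the order
#' of rows in the input.
#'
#' @param frame A single-frame data frame with columns `joint`, `x`, `y`, `z`
#'   and optionally `tracked`.
#' @return A numeric vector of length 60.
#' @export
frame_feature_vector <- function(frame) {
  frame <- coerce_frame(frame)
  if (any(!frame$tracked)) {
    stop("untracked joint, no fallback")
  }
  as.vector(t(as.matrix(frame[, c("x", "y", "z")])))
}

# Feature matrix (n x 60) for a whole clip, with untracked joints
# forward-filled. Frames with a joint that has no tracking history yet are
# returned as NA rows (callers downgrade those frames).
clip_feature_matrix <- function(clip) {
  arr <- clip_arrays(clip)
  fl <- fill_untracked(arr)
  n <- dim(fl$pos)[1]
  X <- matrix(NA_real_, n, 60)
  ok <- rowSums(fl$missing) == 0
  if (any(ok)) {
    # joint-major within frame: (x,y,z) per joint in enum order
    X[ok, ] <- matrix(aperm(fl$pos[ok, , , drop = FALSE], c(1, 3, 2)), sum(ok), 60)
  }
  X
}

#' Fit feature normalization statistics
#'
#' Per-dimension mean and standard deviation over a training feature matrix;
#' the standard scaling applied to skeleton feature vectors before SVM
#' training. Zero-variance dimensions get a standard deviation of 1 (and are
#' recorded) so the transform stays invertible.
#'
#' @param X Numeric matrix, one 60-vector per row.
#' @return A list with `mean`, `sd` (both length-60) and `constant_dims`.
#' @export
fit_normalization <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  # population standard deviation: invariant under duplicating the set
  sd <- sqrt(colMeans(sweep(X, 2, mu)^2))
  const <- sd <= .Machine$double.eps
  sd[const] <- 1
  list(mean = mu, sd = sd, constant_dims = which(const))
}

#' Normalize feature vectors
#'
#' Elementwise `(f - mean) / sd` with statistics from [fit_normalization()].
#'
#' @param X A feature vector or matrix (rows are vectors).
#' @param stats A list with `mean` and `sd`.
#' @return Same shape as `X`.
#' @export
normalize_features <- function(X, stats) {
  if (is.null(dim(X))) {
    (X - stats$mean) / stats$sd
  } else {
    sweep(sweep(as.matrix(X), 2, stats$mean), 2, stats$sd, "/")
  }
}

#' @rdname normalize_features
#' @export
denormalize_features <- function(X, stats) {
  if (is.null(dim(X))) {
    X * stats$sd + stats$mean
  } else {
    sweep(sweep(as.matrix(X), 2, stats$sd, "*"), 2, stats$mean, "+")
  }
}

# Vectorized bone-midpoint centroid over filled positions (n x 20 x 3).
# Bones whose endpoint is missing are dropped (partial flag); if every bone
# has zero length (all joints coincident) the unweighted midpoint mean is
# used, which equals the common point.
centroid_track <- function(pos, missing = NULL, weighted = TRUE) {
  edges <- bone_edges()
  fi <- match(edges$from, joint_names())
  ti <- match(edges$to, joint_names())
  n <- dim(pos)[1]
  a <- pos[, fi, , drop = FALSE]
  b <- pos[, ti, , drop = FALSE]
  mid <- (a + b) / 2
  len <- sqrt(apply((a - b)^2, c(1, 2), sum))
  ok <- matrix(TRUE, n, 19)
  if (!is.null(missing)) ok <- !(missing[, fi, drop = FALSE] |
                                   missing[, ti, drop = FALSE])
  w <- if (weighted) len else matrix(1, n, 19)
  w[!ok] <- 0
  wsum <- rowSums(w)
  degenerate <- wsum <= .Machine$double.eps
  if (any(degenerate)) {
    # coincident joints: fall back to unweighted mean over available midpoints
    w2 <- ok * 1
    w[degenerate, ] <- w2[degenerate, ]
    wsum <- rowSums(w)
  }
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  all_missing <- wsum <= .Machine$double.eps
  for (k in 1:3) out[, k] <- rowSums(w * mid[, , k]) / wsum
  out[all_missing, ] <- NA_real_
  attr(out, "partial") <- if (is.null(missing)) rep(FALSE, n) else
    rowSums(!ok) > 0
  out
}

#' Body centroid of a skeleton frame
#'
#' Center of mass of the 19 bones under a uniform-rod assumption: the
#' bone-length-weighted mean of the bone midpoints. With
#' `weighted = FALSE` the plain mean of the 19 midpoints is returned
#' instead.
#'
#' @param frame A single-frame data frame (`joint`, `x`, `y`, `z`, optionally
#'   `tracked`). Bones with an untracked endpoint are dropped and the result
#'   is flagged partial.
#' @param weighted Weight midpoints by bone length (default) or not.
#' @return Numeric xyz vector with attribute `partial`.
#' @export
body_centroid <- function(frame, weighted = TRUE) {
  frame <- coerce_frame(frame)
  pos <- array(NA_real_, c(1, 20, 3))
  pos[1, , ] <- as.matrix(frame[, c("x", "y", "z")])
  missing <- matrix(!frame$tracked, 1, 20)
  out <- centroid_track(pos, missing, weighted = weighted)
  res <- out[1, ]
  attr(res, "partial") <- attr(out, "partial")[1]
  res
}

# Per-frame body height over filled positions; NA where a chain joint is
# missing. H = trunk chain + mean(left leg chain, right leg chain).
height_track <- function(pos, missing = NULL) {
  ch <- height_chain()
  seg_len <- function(pair) {
    i <- match(pair[1], joint_names())
    j <- match(pair[2], joint_names())
    di <- pos[, i, , drop = FALSE] - pos[, j, , drop = FALSE]
    sqrt(rowSums(matrix(di, dim(pos)[1], 3)^2))
  }
  chain_sum <- function(chain) Reduce(`+`, lapply(chain, seg_len))
  H <- chain_sum(ch$trunk) +
    (chain_sum(ch$leg_left) + chain_sum(ch$leg_right)) / 2
  if (!is.null(missing)) {
    used <- unique(unlist(ch))
    bad <- rowSums(missing[, match(used, joint_names()), drop = FALSE]) > 0
    H[bad] <- NA_real_
  }
  H
}

#' Body height estimate from a skeleton frame
#'
#' Sum of bone lengths along a head-to-foot chain: head to shoulder center to
#' spine to hip center, plus the average over the left and right leg chains
#' (hip center - hip - knee - ankle - foot). Used as the reference height for
#' the head-altitude module.
#'
#' @inheritParams body_centroid
#' @return Height in meters.
#' @export
body_height <- function(frame) {
  frame <- coerce_frame(frame)
  pos <- array(NA_real_, c(1, 20, 3))
  pos[1, , ] <- as.matrix(frame[, c("x", "y", "z")])
  missing <- matrix(!frame$tracked, 1, 20)
  H <- height_track(pos, missing)[1]
  if (is.na(H)) stop("height unavailable")
  H
}

#' Spine vector of a skeleton frame
#'
#' The 3D vector from HIP_CENTER to SHOULDER_CENTER; the body-lean module
#' measures its angle against the floor normal.
#'
#' @inheritParams body_centroid
#' @return Numeric xyz vector.
#' @export
spine_vector <- function(frame) {
  frame <- coerce_frame(frame)
  hc <- frame[frame$joint == "HIP_CENTER", ]
  sc <- frame[frame$joint == "SHOULDER_CENTER", ]
  if (!hc$tracked || !sc$tracked) stop("spine endpoints untracked")
  c(x = sc$x - hc$x, y = sc$y - hc$y, z = sc$z - hc$z)
}
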