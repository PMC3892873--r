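#' Write / read a skeleton clip as JSON lines
#'
#' One header record (`frame_rate`, `p_gt`, `behavior`, `clip_id`) followed
#' by one JSON object per frame with `frame`, `t`, and a `[x, y, z,
#' tracked]` quadruple per joint. All coordinates in meters.
#'
#' @param clip A [skeleton_clip()].
#' @param path File path (`.jsonl`).
#' @return `write_clip_jsonl` returns `path` invisibly; `read_clip_jsonl`
#'   returns a [skeleton_clip()].
#' @export
write_clip_jsonl <- function(clip, path) {
  header <- list(record = "header", frame_rate = clip$frame_rate,
                 p_gt = clip$p_gt, behavior = clip$behavior,
                 clip_id = clip$clip_id)
  lines <- jsonlite::toJSON(header, auto_unbox = TRUE, null = "null",
                            digits = NA)
  fr <- clip$frames
  for (f in unique(fr$frame)) {
    sub <- fr[fr$frame == f, ]
    joints <- stats::setNames(
      purrr::pmap(list(sub$x, sub$y, sub$z, sub$tracked),
                  function(x, y, z, tr) list(x, y, z, tr)),
      sub$joint)
    rec <- c(list(frame = f, t = sub$t[1]), joints)
    lines <- c(lines, jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_clip_jsonl
#' @export
read_clip_jsonl <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  frames <- purrr::map_dfr(lines[-1], function(ln) {
    rec <- jsonlite::fromJSON(ln)
    jn <- setdiff(names(rec), c("frame", "t"))
    tibble::tibble(
      frame = rec$frame, t = rec$t, joint = jn,
      x = unname(vapply(rec[jn], function(v) as.numeric(v[[1]]), numeric(1))),
      y = unname(vapply(rec[jn], function(v) as.numeric(v[[2]]), numeric(1))),
      z = unname(vapply(rec[jn], function(v) as.numeric(v[[3]]), numeric(1))),
      tracked = unname(vapply(rec[jn], function(v) as.logical(v[[4]]),
                              logical(1)))
    )
  })
  skeleton_clip(frames, frame_rate = header$frame_rate,
                p_gt = header$p_gt, behavior = header$behavior,
                clip_id = header$clip_id)
}

#' Write / read a skeleton clip as flat CSV
#'
#' Long-format dialect: columns `frame`, `t`, `joint`, `x`, `y`, `z`,
#' `tracked`. Clip metadata is not carried; pass it on read.
#'
#' @param clip A [skeleton_clip()].
#' @param path File path (`.csv`).
#' @param frame_rate,p_gt,behavior,clip_id Metadata for the read clip.
#' @export
write_clip_csv <- function(clip, path) {
  readr::write_csv(clip$frames, path)
  invisible(path)
}

#' @rdname write_clip_csv
#' @export
read_clip_csv <- function(path, frame_rate = 30, p_gt = NULL,
                          behavior = NULL, clip_id = NULL) {
  skeleton_clip(readr::read_csv(path, show_col_types = FALSE),
                frame_rate = frame_rate, p_gt = p_gt, behavior = behavior,
                clip_id = clip_id)
}

#' Read / write 3D point clouds
#'
#' CSV (`x`, `y`, `z` header) and ASCII PLY, meters.
#'
#' @param path File path.
#' @param cloud A data frame with `x`, `y`, `z`.
#' @export
read_cloud_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)[, c("x", "y", "z")]
}

#' @rdname read_cloud_csv
#' @export
write_cloud_csv <- function(cloud, path) {
  readr::write_csv(tibble::as_tibble(cloud)[, c("x", "y", "z")], path)
  invisible(path)
}

#' @rdname read_cloud_csv
#' @export
write_cloud_ply <- function(cloud, path) {
  cloud <- tibble::as_tibble(cloud)
  lines <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(cloud)),
             "property float x", "property float y", "property float z",
             "end_header",
             sprintf("%.9g %.9g %.9g", cloud$x, cloud$y, cloud$z))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_cloud_csv
#' @export
read_cloud_ply <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "ply")) stop("not a PLY file")
  endh <- which(lines == "end_header")[1]
  nv_line <- grep("^element vertex", lines[seq_len(endh)], value = TRUE)[1]
  nv <- as.integer(strsplit(nv_line, " ")[[1]][3])
  vals <- utils::read.table(text = lines[(endh + 1):(endh + nv)])
  tibble::tibble(x = vals[[1]], y = vals[[2]], z = vals[[3]])
}

#' Read / write depth profiles
#'
#' CSV with columns `frame`, `upper_mean_depth`, `lower_mean_depth`
#' (meters).
#'
#' @param profile A depth-profile tibble.
#' @param path File path.
#' @export
write_depth_profile_csv <- function(profile, path) {
  readr::write_csv(profile, path)
  invisible(path)
}

#' @rdname write_depth_profile_csv
#' @export
read_depth_profile_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Serialize / restore models and parameters as JSON
#'
#' Posture models, fusion models and local-parameter tables round-trip
#' through plain JSON so trained pipelines can be stored as text.
#'
#' @param object A `posture_model`, `fusion_model` or [local_params()]
#'   tibble.
#' @param path File path (`.json`).
#' @export
write_model_json <- function(object, path) {
  if (inherits(object, "posture_model")) {
    payload <- list(type = "posture_model",
                    sv = object$sv, coefs = object$coefs, rho = object$rho,
                    kernel_degree = object$kernel_degree, cost = object$cost,
                    feature_mask = object$feature_mask,
                    norm_mean = object$norm_stats$mean,
                    norm_sd = object$norm_stats$sd,
                    constant_dims = object$norm_stats$constant_dims)
  } else if (inherits(object, "wmean_fusion")) {
    payload <- list(type = "wmean_fusion", beta = object$beta,
                    fit_error = object$fit_error, T = object$T)
  } else if (inherits(object, "svm_fusion")) {
    payload <- list(type = "svm_fusion", cost = object$cost,
                    gamma = object$gamma, T = object$T,
                    cv_accuracy = object$cv_accuracy,
                    sv = object$sv, coefs = object$coefs, rho = object$rho)
  } else if (is.data.frame(object) &&
             all(c("module", "alpha") %in% names(object))) {
    payload <- list(type = "local_params",
                    module = object$module, alpha = object$alpha)
  } else {
    stop("unsupported object")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  switch(p$type,
    posture_model = structure(
      list(sv = as.matrix(p$sv), coefs = as.numeric(p$coefs),
           rho = as.numeric(p$rho), kernel_degree = p$kernel_degree,
           cost = p$cost, feature_mask = as.integer(p$feature_mask),
           norm_stats = list(mean = as.numeric(p$norm_mean),
                             sd = as.numeric(p$norm_sd),
                             constant_dims = as.integer(p$constant_dims))),
      class = "posture_model"),
    wmean_fusion = structure(
      list(scheme = "weighted_mean", beta = p$beta,
           fit_error = p$fit_error, T = p$T),
      class = c("wmean_fusion", "fusion_model")),
    svm_fusion = structure(
      list(scheme = "svm", cost = p$cost, gamma = p$gamma, T = p$T,
           cv_accuracy = p$cv_accuracy, sv = as.matrix(p$sv),
           coefs = as.numeric(p$coefs), rho = as.numeric(p$rho)),
      class = c("svm_fusion", "fusion_model")),
    local_params = local_params(tibble::tibble(module = p$module,
                                               alpha = p$alpha)),
    stop("unknown model type: ", p$type)
  )
}
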