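#' PCA-based artifact projector (signal-space projection)
#'
#' Stereotyped physiological artifacts (heartbeat, eye blinks) are removed
#' by orthogonal projection: epochs are extracted around detected artifact
#' events, averaged time-locked to the event, and the top principal spatial
#' components of the event-locked average form an orthonormal projector
#' which is then regressed out of the continuous data.
#'
#' @param ts a [roi_ts()] (or any channels-by-samples recording wrapped in
#'   one) containing the artifact.
#' @param events integer sample indices of artifact events (>= 10 required).
#' @param half_width_ms epoch half-width around each event, in ms.
#' @param k number of spatial components to retain (default 1 per artifact
#'   type); `k = 0` yields an identity (no-op) projector.
#' @return An object of class `ssp_projector`: list with `components`
#'   (channels x k orthonormal matrix) and `k`.
#' @export
build_projector <- function(ts, events, half_width_ms = 100, k = 1) {
  stopifnot(inherits(ts, "roi_ts"))
  X <- ts$data
  if (k > nrow(X)) stop("k = ", k, " exceeds the channel count ", nrow(X))
  if (k == 0)
    return(structure(list(components = matrix(0, nrow(X), 0), k = 0L),
                     class = "ssp_projector"))
  if (length(events) < 10)
    stop("need at least 10 artifact epochs, got ", length(events))
  hw <- round(half_width_ms / 1000 * ts$fs)
  if (any(events - hw < 1 | events + hw > ncol(X)))
    stop("artifact epochs extend outside the recording")
  win <- (-hw):hw
  avg <- matrix(0, nrow(X), length(win))
  for (e in events) avg <- avg + X[, e + win, drop = FALSE]
  avg <- avg / length(events)
  sv <- svd(avg - rowMeans(avg), nu = k, nv = 0)
  structure(list(components = sv$u, k = as.integer(k)), class = "ssp_projector")
}

#' @export
print.ssp_projector <- function(x, ...) {
  cat(sprintf("<ssp_projector> %d component(s) over %d channels\n",
              x$k, nrow(x$components)))
  invisible(x)
}

#' Apply an orthogonal projector
#'
#' Projects the recording onto the orthogonal complement of the artifact
#' subspace: `X_clean = (I - U U') X`. The operation is idempotent and the
#' output is orthogonal to every projector component at every sample.
#'
#' @param ts a [roi_ts()].
#' @param proj an `ssp_projector` from [build_projector()] with matching
#'   channel dimension.
#' @return The cleaned [roi_ts()].
#' @export
apply_projector <- function(ts, proj) {
  stopifnot(inherits(ts, "roi_ts"), inherits(proj, "ssp_projector"))
  U <- proj$components
  if (nrow(U) != nrow(ts$data))
    stop("projector has ", nrow(U), " channels but data has ", nrow(ts$data))
  out <- ts
  if (proj$k > 0) out$data <- ts$data - U %*% (t(U) %*% ts$data)
  out
}
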