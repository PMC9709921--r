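# IFP_CS: cosine-similarity scoring of per-frame fingerprints against the
# equilibrated reference, and per-window aggregation.

#' Interaction-fingerprint cosine similarity score
#'
#' Compares a query fingerprint with the reference fingerprint of the
#' equilibrated complex:
#' \deqn{IFP_{CS} = -\frac{q \cdot ref}{\lVert q\rVert \, \lVert ref\rVert}}
#' The score ranges from -1 (the query reproduces the reference interaction
#' pattern exactly, up to extra bits) to 0 (every interaction determinant of
#' the reference is lost). A query with no set bits scores 0 by convention:
#' cosine similarity is undefined for a null vector, and an interactionless
#' frame is precisely the "all determinants lost" state.
#'
#' @param query,reference `interaction_fingerprint` objects (or plain 0/1
#'   vectors) of equal length and identical residue/channel order.
#' @return Numeric score in `[-1, 0]`.
#' @export
ifp_cs <- function(query, reference) {
  if (length(query) != length(reference))
    usage_error("query and reference fingerprints differ in length")
  ro_q <- attr(query, "residue_order"); ro_r <- attr(reference, "residue_order")
  if (!is.null(ro_q) && !is.null(ro_r) && !identical(ro_q, ro_r))
    usage_error("query and reference fingerprints have different residue order")
  q <- as.numeric(query); r <- as.numeric(reference)
  nr <- sqrt(sum(r^2))
  if (nr == 0)
    config_error("reference fingerprint has no set bits (no protein-ligand contacts)")
  nq <- sqrt(sum(q^2))
  if (nq == 0) return(0)
  -sum(q * r) / (nq * nr)
}

#' Reference fingerprint from an equilibration trajectory
#'
#' The reference interaction pattern is taken from the final frame of the
#' (last) equilibration stage: the fully equilibrated bound pose.
#'
#' @param equilibration_traj A [trajectory()] from the backend's equilibration.
#' @param system A [molecular_system()].
#' @param features [perceive_features()] output or a [fingerprint_context()].
#' @param thresholds See [interaction_thresholds()].
#' @return An `interaction_fingerprint`; errors if it has no set bits.
#' @export
reference_fingerprint <- function(equilibration_traj, system, features,
                                  thresholds = interaction_thresholds()) {
  if (!length(equilibration_traj))
    usage_error("equilibration trajectory is empty")
  fp <- compute_fingerprint(
    equilibration_traj$coords[[length(equilibration_traj)]],
    system, features, thresholds
  )
  if (sum(fp) == 0)
    config_error("reference frame shows no protein-ligand contacts")
  fp
}

#' Score every frame of a trajectory against a reference fingerprint
#'
#' @param traj A [trajectory()].
#' @param system A [molecular_system()].
#' @param features [perceive_features()] output or a [fingerprint_context()].
#' @param reference The reference `interaction_fingerprint`.
#' @param stride Score every `stride`-th frame (default every frame).
#' @param window_id Integer tag carried into the result.
#' @return Object of class `similarity_series`: data.frame with columns
#'   `frame`, `time`, `temperature`, `ifp_cs`; attribute `contact_counts`
#'   (per-residue count of scored frames with any bit set, used to rank the
#'   most contacted residues).
#' @export
score_trajectory <- function(traj, system, features, reference, stride = 1L,
                             window_id = NA_integer_) {
  ctx <- if (inherits(features, "fingerprint_context")) features
         else fingerprint_context(system, features)
  frames <- seq(1, length(traj), by = stride)
  counts <- integer(ctx$n_res)
  vals <- numeric(length(frames))
  for (k in seq_along(frames)) {
    fp <- compute_fingerprint(traj$coords[[frames[k]]], system, ctx)
    vals[k] <- ifp_cs(fp, reference)
    m <- matrix(unclass(fp), ncol = 8, byrow = TRUE)
    counts <- counts + as.integer(rowSums(m) > 0)
  }
  out <- data.frame(frame = frames, time = traj$time[frames],
                    temperature = traj$temperature[frames], ifp_cs = vals)
  structure(out, contact_counts = stats::setNames(counts, ctx$residue_order),
            window_id = window_id,
            class = c("similarity_series", "data.frame"))
}

#' Average IFP_CS of a scored window
#'
#' @param series A `similarity_series` (or any data.frame with an `ifp_cs`
#'   column, or a bare numeric vector of scores).
#' @return Arithmetic mean of the per-frame scores.
#' @export
window_average <- function(series) {
  vals <- if (is.numeric(series)) series else series$ifp_cs
  if (is.null(vals) || !length(vals))
    usage_error("cannot average an empty similarity series")
  mean(vals)
}
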