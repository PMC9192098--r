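#' Fixed ECG-to-VCG lead transform matrix
#'
#' The 3 x 8 Kors-style regression matrix mapping the 8 independent ECG leads
#' (I, II, V1--V6) onto the orthogonal VCG leads (Vx, Vy, Vz). Leads III and
#' the augmented leads are linear combinations of I and II and carry no extra
#' information, so the transform omits them.
#'
#' @format Numeric matrix, rows `Vx, Vy, Vz`, columns `I, II, V1..V6`.
#' @export
VCG_TRANSFORM <- matrix(
  c( 0.38, -0.07, -0.13,  0.05, -0.01,  0.14,  0.06,  0.54,
    -0.07,  0.93,  0.06, -0.02, -0.05,  0.06, -0.17,  0.13,
     0.11, -0.23, -0.43, -0.06, -0.14, -0.20, -0.11,  0.31),
  nrow = 3, byrow = TRUE,
  dimnames = list(c("Vx", "Vy", "Vz"),
                  c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")))

#' Derive the 3-lead VCG from a 12-lead ECG record
#'
#' Applies the fixed linear transform [VCG_TRANSFORM] sample-by-sample. The
#' record must contain leads I, II and V1--V6; any other leads present are
#' ignored. The operation is exactly linear: unit amplitude on a single input
#' lead reproduces the corresponding matrix column on the three outputs.
#'
#' @param rec a `multi_lead_record` containing at least the 8 required leads.
#' @return A `vcg_record` with the same `fs` and sample count.
#' @export
ecg_to_vcg <- function(rec) {
  stopifnot(inherits(rec, "multi_lead_record"))
  need <- colnames(VCG_TRANSFORM)
  missing <- setdiff(need, rec$lead_names)
  if (length(missing)) {
    stop(sprintf("lead not found: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  xyz <- rec$samples[, need, drop = FALSE] %*% t(VCG_TRANSFORM)
  vcg_record(xyz, fs = rec$fs, source_record_id = rec$record_id)
}
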