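#' The 19-electrode 10-20 montage
#'
#' Canonical ordered electrode labels of the international 10-20 system as used
#' for clinical resting-state EEG: Fp1, Fp2, F3, F4, C3, C4, P3, P4, O1, O2,
#' F7, F8, T3, T4, T5, T6, Fz, Cz, Pz. Every result grid in the package
#' (multiscale-entropy profiles, PSD matrices, post-hoc test grids) indexes its
#' electrode axis in this fixed order.
#'
#' @return Character vector of 19 electrode labels.
#' @export
#' @examples
#' montage_1020()
montage_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

# Check labels against the canonical montage; returns the canonical ordering of
# the supplied labels. Missing required labels abort with their names.
check_montage <- function(labels, require_full = FALSE) {
  mont <- montage_1020()
  unknown <- setdiff(labels, mont)
  if (length(unknown) > 0)
    stop("unknown electrode label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (require_full) {
    missing <- setdiff(mont, labels)
    if (length(missing) > 0)
      stop("montage is missing electrode(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  mont[mont %in% labels]
}
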