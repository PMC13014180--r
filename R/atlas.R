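#' Canonical sulcus atlas
#'
#' The package works on a fixed atlas of 40 cortical sulci: 20 named sulci in
#' each hemisphere. All matrices (SPNs, effect maps, parcellations) are ordered
#' by this list unless a user atlas overrides it.
#'
#' @param n_per_hemi number of sulci per hemisphere (default 20).
#' @return character vector of sulcus labels, left hemisphere first, each
#'   label suffixed `_L` / `_R`.
#' @export
canonical_sulci <- function(n_per_hemi = 20L) {
  base <- c(
    "central", "precentral", "postcentral", "superior_frontal",
    "inferior_frontal", "intermediate_frontal", "orbital", "olfactory",
    "anterior_cingulate", "posterior_cingulate", "superior_temporal",
    "inferior_temporal", "occipital_temporal_lateral", "collateral",
    "calcarine", "parieto_occipital", "intraparietal", "occipital",
    "subparietal", "insula"
  )
  if (n_per_hemi <= length(base)) {
    nm <- base[seq_len(n_per_hemi)]
  } else {
    extra <- sprintf("sulcus_%02d", seq_len(n_per_hemi - length(base)))
    nm <- c(base, extra)
  }
  c(paste0(nm, "_L"), paste0(nm, "_R"))
}

#' Default sulcus annotation
#'
#' Annotation table carrying, for each canonical sulcus, its prior
#' linear/complex class and its position on the reference linear-to-complex
#' axis (in \[-1, 1\]; -1 = most linear, +1 = most complex). The default is a
#' stylized bimodal axis: half the sulci sit on the linear side, half on the
#' complex side, with homologous left/right sulci sharing a position. This is
#' the planted truth used by the synthetic cohort generator and the class
#' annotation consumed by the contraction test.
#'
#' @param sulci character vector of sulcus labels (default [canonical_sulci()]).
#' @return data.frame with columns `sulcus`, `hemisphere`, `class`
#'   (`"linear"`/`"complex"`) and `axis` (numeric in \[-1, 1\]).
#' @export
default_sulcus_annotation <- function(sulci = canonical_sulci()) {
  n <- length(sulci)
  hemi <- ifelse(grepl("_R$", sulci), "R", "L")
  n_per_hemi <- n %/% 2L
  # homologous pairs share an axis position; alternate linear/complex so both
  # classes are spread over the name list rather than blocked
  half <- n_per_hemi %/% 2L
  lin_pos <- seq(-1, -0.2, length.out = half)
  cpl_pos <- seq(0.2, 1, length.out = n_per_hemi - half)
  pos <- numeric(n_per_hemi)
  pos[seq(1L, n_per_hemi, by = 2L)] <- lin_pos
  pos[seq(2L, n_per_hemi, by = 2L)] <- cpl_pos
  axis <- rep(pos, 2L)
  data.frame(
    sulcus = sulci,
    hemisphere = hemi,
    class = ifelse(axis < 0, "linear", "complex"),
    axis = axis,
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
most_complex_sulcus <- function(annotation) {
  annotation$sulcus[which.max(annotation$axis)]
}

#' @keywords internal
most_linear_sulcus <- function(annotation) {
  annotation$sulcus[which.min(annotation$axis)]
}
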