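# Shared fixture builders. Everything is generated in code; no data files.

# Slide table with prescribed A and M (log2 scale), optional backgrounds.
# With bg = 0 and background = "ignore" the working intensities reproduce
# A and M exactly.
slide_from_am <- function(a, m, gene_id = NULL, bg = 0) {
  n <- length(a)
  if (is.null(gene_id)) gene_id <- sprintf("g%04d", seq_len(n))
  data.frame(
    spot_id = sprintf("spot%04d", seq_len(n)),
    gene_id = gene_id,
    ch1_fg = 2^(a + m / 2) + bg,
    ch1_bg = rep(bg, n),
    ch2_fg = 2^(a - m / 2) + bg,
    ch2_bg = rep(bg, n),
    stringsAsFactors = FALSE
  )
}

# Oriented log2 ratios recomputed directly from a raw slide table,
# independent of the preprocessing module (background subtracted exactly).
raw_oriented_ratios <- function(slide, orientation) {
  m <- log2(slide$ch1_fg - slide$ch1_bg) - log2(slide$ch2_fg - slide$ch2_bg)
  if (orientation == "patient_in_ch1") m else -m
}

# Tiny two-patient design for unit tests.
tiny_design <- function() {
  data.frame(
    slide_id = c("s01", "s02", "s03", "s04"),
    patient_id = c("p1", "p1", "p2", "p2"),
    pair_id = c("pair1", "pair1", "pair2", "pair2"),
    orientation = c("patient_in_ch1", "patient_in_ch2",
                    "patient_in_ch1", "patient_in_ch2"),
    stringsAsFactors = FALSE
  )
}
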