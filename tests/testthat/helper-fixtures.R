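# Small in-code fixtures.

tiny_library <- function() {
  data.frame(
    guide_id = c("geneA_sg1", "geneA_sg2", "geneB_sg1", "geneB_sg2"),
    gene_id = c("geneA", "geneA", "geneB", "geneB"),
    sequence = c("ACGTACGTACGTACGTACGT",
                 "TTGCATTGCATTGCATTGCA",
                 "GGGGCCCCAAAATTTTACGT",
                 "CATCATCATCATCATCATCA"),
    stringsAsFactors = FALSE)
}

tiny_sheet <- function() {
  data.frame(
    sample_id = c("control_rep1", "control_rep2", "treated_rep1", "treated_rep2"),
    barcode = c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT"),
    condition = c("control", "control", "treated", "treated"),
    replicate = c("rep1", "rep2", "rep1", "rep2"),
    stringsAsFactors = FALSE)
}

# A read with the key starting at `offset` (1-based) followed by `guide_seq`.
layout_read <- function(guide_seq, offset = 16L, barcode = "AAAAAA",
                        g_before = FALSE, key = "CGAAACACC",
                        read_length = 75L, filler = "T") {
  stuffer <- strrep(filler, offset - 1L - nchar(barcode))
  core <- paste0(barcode, stuffer, key, if (g_before) "G" else "", guide_seq)
  paste0(core, strrep(filler, max(read_length - nchar(core), 0L)))
}
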