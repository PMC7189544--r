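# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_genome <- function() {
  fixture("small_genome", function() make_genome(seed = 7))
}

small_readset <- function() {
  fixture("small_readset", function() {
    make_blcl_readset(small_genome(), n_pairs = 6000, seed = 11)
  })
}

small_calls <- function() {
  fixture("small_calls", function() {
    rs <- small_readset()
    call_eremaps(rs$psms, rs$alignments, rs$repeats, rs$genes, rs$genome,
                 rs$transcripts, rs$tpm, rs$variants, rs$cds_start)
  })
}

small_panel <- function() {
  fixture("small_panel", function() {
    make_tissue_panel(n_tissues = 8, n_families = 60, n_restricted = 6,
                      samples_per_tissue = 3, seed = 5)
  })
}

# tiny expression tibble from a matrix literal
expr_tbl <- function(m, unit = "TPM") {
  tbl <- tibble::as_tibble(m)
  tbl <- dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)), tbl)
  attr(tbl, "unit") <- unit
  tbl
}
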