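#' Reference protein sequences for the ten cassette gene families
#'
#' Deterministic synthetic stand-ins for the K-12-derived query set (real
#' reference proteomes are not bundled): random amino-acid sequences drawn
#' once under a fixed internal seed, with family-specific lengths roughly
#' ordered like the real proteins (transporters and the sulfoquinovosidase
#' longer, the regulator shorter). The same call always returns the same
#' sequences, so they behave like a packaged reference.
#'
#' @return A [query_family_set()] of the ten families in reference order.
#' @export
yih_query_proteins <- function() {
  lens <- c(ompL = 110L, yihO = 130L, yihP = 130L, yihQ = 150L,
            yihR = 100L, yihS = 120L, yihT = 110L, yihU = 90L,
            yihV = 95L, yihW = 85L)
  aa <- setdiff(AA_ALPHABET, "X")
  seqs <- with_seed(104729L, {
    vapply(lens, function(L) paste(sample(aa, L, replace = TRUE),
                                   collapse = ""), character(1))
  })
  query_family_set(seqs)
}

#' Reference protein sequences for the UOG backbone
#'
#' Deterministic synthetic marker proteins, one per universal single-copy
#' orthologous group, generated under a fixed internal seed (distinct from
#' the cassette query seed).
#'
#' @param n Number of UOGs (default 238).
#' @param len Protein length in residues (default 90).
#' @return Named character vector `UOG001` ... `UOGnnn`.
#' @export
uog_reference_proteins <- function(n = 238, len = 90) {
  aa <- setdiff(AA_ALPHABET, "X")
  seqs <- with_seed(7919L, {
    vapply(seq_len(n), function(i) paste(sample(aa, len, replace = TRUE),
                                         collapse = ""), character(1))
  })
  setNames(seqs, sprintf("UOG%03d", seq_len(n)))
}
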