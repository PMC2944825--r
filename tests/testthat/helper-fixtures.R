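# Hand-built toy fixture: 3 proteins, 2 domains, 5 SNPs whose classes were
# worked out by hand while constructing the sequences (2 domain-altering,
# 2 domain SNPs, 1 outside).

toy_domains <- function() {
  pat <- parse_pattern("C-x-V-[KR]", domain_id = "TOYPAT")
  sc <- matrix(-2, nrow = 3, ncol = 20, dimnames = list(NULL, aa_alphabet()))
  sc[1, "M"] <- 3; sc[2, "K"] <- 3; sc[3, "T"] <- 3
  sc[3, "S"] <- 3  # benign alternative at position 3
  prf <- profile_def("TOYPRF", sc, gap_open = -5, gap_extend = -1, cutoff = 6)
  structure(list(TOYPAT = pat, TOYPRF = prf), class = "domain_set")
}

toy_proteome <- function() {
  tibble::tibble(
    protein_id = c("P1", "P2", "P3"),
    gene_symbol = c("GENE1", "GENE2", "GENE3"),
    #                 123456789           pattern CAVK at 2-5 of P1
    sequence = c("ACAVKGGGG",
                 #           profile consensus MKT at 4-6 of P2
                 "GGGMKTGGG",
                 "GGGGGGGGG")
  )
}

# snp_id -> expected (status, mechanism) at dd_cutoff = 0.10:
#   s1 P1:2 C->A   breaks the exact C element, no surviving match -> da/pattern_loss
#   s2 P1:3 A->G   wildcard position, match survives              -> d_snp
#   s3 P2:4 M->G   consensus M lost: MS 9 -> 6 (KT tail, free end
#                  deletion of row 1), DD = 1/3 >= 0.10            -> da/profile_distortion
#   s4 P2:6 T->S   benign alternative scores equally, DD 0        -> d_snp
#   s5 P3:5 G->A   no domain anywhere                             -> outside
toy_snps <- function() {
  tibble::tibble(
    snp_id = paste0("s", 1:5),
    protein_id = c("P1", "P1", "P2", "P2", "P3"),
    position = c(2L, 3L, 4L, 6L, 5L),
    ref_aa = c("C", "A", "M", "T", "G"),
    alt_aa = c("A", "G", "G", "S", "A")
  )
}

toy_expected_status <- function() {
  c(s1 = "da_snp", s2 = "d_snp", s3 = "da_snp", s4 = "d_snp", s5 = "outside")
}

# A small generated universe shared across tests (cached per session). The
# DA fraction is raised above the study default so both damaging mechanisms
# (pattern loss, profile distortion) are exercised at this small scale.
small_universe <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_universe(
        universe_config(seed = 42, n_proteins = 80, frac_da_given_domain = 0.25)
      )
    }
    cache
  }
})
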