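#' Configuration for the synthetic-universe generator
#'
#' Bundles and validates every tunable of [generate_universe()]. The default
#' proportions mirror the gross shape of a proteome-wide missense-SNP scan:
#' about one SNP in five falls inside a matched domain, about one in-domain
#' SNP in twenty is domain-altering, and about 6% of in-domain SNPs carry a
#' disease annotation at baseline.
#'
#' @param seed Integer seed; a seeded run is byte-reproducible.
#' @param n_proteins Number of proteins (default 300).
#' @param protein_length Length range, inclusive (default `c(80, 400)`).
#' @param n_pattern_domains,n_profile_domains Number of pattern / profile
#'   domain definitions (defaults 6 and 6).
#' @param n_motifs Number of linear-motif definitions (default 6).
#' @param snps_per_protein Mean of the per-protein Poisson SNP count
#'   (default 2).
#' @param frac_snp_in_domain Target overall fraction of SNPs placed inside a
#'   planted domain (default 0.2).
#' @param frac_da_given_domain Fraction of in-domain SNPs planted as
#'   domain-altering (default 0.05).
#' @param disease_base_rate Baseline per-SNP disease-annotation probability
#'   (default 0.06).
#' @param disease_odds_ratio_da Odds ratio (>= 1) multiplying the disease
#'   odds of intended domain-altering SNPs (default 2).
#' @param n_binding_rules Number of planted signature-pair binding rules
#'   (default 5).
#' @param edge_density Expected number of PPI edges per protein (default 2).
#' @param rule_fidelity Fraction of edges generated by planted rules, the
#'   rest being uniform noise (default 0.9; must be in (0.5, 1]).
#' @param dd_cutoff DD cutoff the generator guarantees its damaging profile
#'   SNPs to exceed (default 0.10).
#' @param frac_protein_with_domain Probability a protein carries a planted
#'   domain instance (default 0.7).
#' @param frac_protein_with_motif Probability a protein carries a planted
#'   motif instance instead (default 0.25). Planted signatures are mutually
#'   exclusive: a protein carries at most one, so that every rule-generated
#'   PPI edge is attributable to exactly one planted rule and the
#'   random-partner null holds for non-planted signature pairs.
#' @param frac_rules_in_reference Probability each planted rule is included
#'   in the reference pair lists (default 1).
#' @param n_decoy_pairs Number of non-planted decoy pairs added to the
#'   reference lists (default 10).
#' @return A validated list of class `universe_config`.
#' @export
universe_config <- function(seed,
                            n_proteins = 300L,
                            protein_length = c(80L, 400L),
                            n_pattern_domains = 6L,
                            n_profile_domains = 6L,
                            n_motifs = 6L,
                            snps_per_protein = 2,
                            frac_snp_in_domain = 0.2,
                            frac_da_given_domain = 0.05,
                            disease_base_rate = 0.06,
                            disease_odds_ratio_da = 2.0,
                            n_binding_rules = 5L,
                            edge_density = 2.0,
                            rule_fidelity = 0.9,
                            dd_cutoff = 0.10,
                            frac_protein_with_domain = 0.7,
                            frac_protein_with_motif = 0.25,
                            frac_rules_in_reference = 1.0,
                            n_decoy_pairs = 10L) {
  cfg <- list(
    seed = as.integer(seed), n_proteins = as.integer(n_proteins),
    protein_length = as.integer(protein_length),
    n_pattern_domains = as.integer(n_pattern_domains),
    n_profile_domains = as.integer(n_profile_domains),
    n_motifs = as.integer(n_motifs),
    snps_per_protein = snps_per_protein,
    frac_snp_in_domain = frac_snp_in_domain,
    frac_da_given_domain = frac_da_given_domain,
    disease_base_rate = disease_base_rate,
    disease_odds_ratio_da = disease_odds_ratio_da,
    n_binding_rules = as.integer(n_binding_rules),
    edge_density = edge_density,
    rule_fidelity = rule_fidelity,
    dd_cutoff = dd_cutoff,
    frac_protein_with_domain = frac_protein_with_domain,
    frac_protein_with_motif = frac_protein_with_motif,
    frac_rules_in_reference = frac_rules_in_reference,
    n_decoy_pairs = as.integer(n_decoy_pairs)
  )
  fracs <- c("frac_snp_in_domain", "frac_da_given_domain", "disease_base_rate",
             "frac_protein_with_domain", "frac_protein_with_motif",
             "frac_rules_in_reference")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0("`", f, "` must be in [0, 1]"))
  }
  if (cfg$disease_odds_ratio_da < 1) abort("`disease_odds_ratio_da` must be >= 1")
  if (cfg$rule_fidelity <= 0.5 || cfg$rule_fidelity > 1) {
    abort("`rule_fidelity` must be in (0.5, 1]")
  }
  if (cfg$dd_cutoff <= 0 || cfg$dd_cutoff > 1) abort("`dd_cutoff` must be in (0, 1]")
  if (length(cfg$protein_length) != 2L || cfg$protein_length[1] > cfg$protein_length[2]) {
    abort("`protein_length` must be an increasing pair")
  }
  # the longest plantable instance must fit in the shortest protein
  if (cfg$protein_length[1] < 40L) {
    abort("minimum protein length must be >= 40 to fit planted instances")
  }
  if (cfg$n_proteins < 2L) abort("`n_proteins` must be >= 2")
  structure(cfg, class = "universe_config")
}

rletter <- function(n, exclude = character()) {
  sample(setdiff(AA_ALPHABET, exclude), n, replace = TRUE)
}

# Per-position probability that a random uniform sequence window matches
# the element list (product of class sizes / 20; wildcards contribute 1).
pattern_chance_prob <- function(kinds, class_sizes) {
  prod(ifelse(kinds == "wildcard", 1, class_sizes / 20))
}

# A plantable pattern domain: fixed-length elements (repeats only on
# wildcards, fixed counts) so the consensus instance maps 1:1 onto element
# offsets, with at least one damaging-capable and one benign-capable offset.
# Domain presence must be attributable to planting, so candidate element
# compositions are redrawn until the expected number of chance matches over
# the whole proteome (`scan_positions` residues) falls below ~0.3.
gen_pattern_domain <- function(id, scan_positions) {
  for (attempt in 1:200) {
    n_el <- sample(4:7, 1)
    kinds <- c("exact", "exact", "exact", "any_of", "wildcard",
               sample(c("exact", "any_of", "none_of", "wildcard"),
                      max(0L, n_el - 5L), replace = TRUE,
                      prob = c(0.35, 0.3, 0.15, 0.2)))
    sizes <- vapply(kinds, function(k) {
      switch(k, exact = 1, any_of = sample(2:3, 1),
             none_of = 20 - sample(1:3, 1), wildcard = 20)
    }, numeric(1))
    if (pattern_chance_prob(kinds, sizes) * scan_positions <= 0.3) break
  }
  ord <- sample(length(kinds))  # shuffle element order
  kinds <- kinds[ord]
  sizes <- sizes[ord]
  consensus <- character()
  benign <- list()     # list of (offset, alts)
  damaging <- list()
  parts <- character()
  offset <- 0L
  for (e in seq_along(kinds)) {
    kind <- kinds[e]
    if (kind == "exact") {
      l <- rletter(1)
      parts <- c(parts, l)
      consensus <- c(consensus, l)
      offset <- offset + 1L
      damaging[[length(damaging) + 1L]] <- list(offset = offset,
                                                alts = setdiff(AA_ALPHABET, l))
    } else if (kind == "any_of") {
      cls <- sort(sample(AA_ALPHABET, sizes[e]))
      l <- sample(cls, 1)
      parts <- c(parts, paste0("[", paste(cls, collapse = ""), "]"))
      consensus <- c(consensus, l)
      offset <- offset + 1L
      damaging[[length(damaging) + 1L]] <- list(offset = offset,
                                                alts = setdiff(AA_ALPHABET, cls))
      ben_alts <- setdiff(cls, l)
      if (length(ben_alts) > 0L) {
        benign[[length(benign) + 1L]] <- list(offset = offset, alts = ben_alts)
      }
    } else if (kind == "none_of") {
      forb <- sort(sample(AA_ALPHABET, 20L - sizes[e]))
      allowed <- setdiff(AA_ALPHABET, forb)
      l <- sample(allowed, 1)
      parts <- c(parts, paste0("{", paste(forb, collapse = ""), "}"))
      consensus <- c(consensus, l)
      offset <- offset + 1L
      damaging[[length(damaging) + 1L]] <- list(offset = offset, alts = forb)
      benign[[length(benign) + 1L]] <- list(offset = offset,
                                            alts = setdiff(allowed, l))
    } else { # wildcard
      rep_n <- if (runif(1) < 0.25) sample(2:3, 1) else 1L
      parts <- c(parts, if (rep_n == 1L) "x" else paste0("x(", rep_n, ")"))
      for (r in seq_len(rep_n)) {
        l <- rletter(1)
        consensus <- c(consensus, l)
        offset <- offset + 1L
        benign[[length(benign) + 1L]] <- list(offset = offset,
                                              alts = setdiff(AA_ALPHABET, l))
      }
    }
  }
  def <- parse_pattern(paste(parts, collapse = "-"), domain_id = id)
  list(def = def, kind = "pattern", consensus = paste(consensus, collapse = ""),
       benign = benign, damaging = damaging)
}

# A plantable profile domain. Consensus residues score 2 except one internal
# high-weight position scoring 4 (the damaging target: substituting it drops
# the matching score by 6, i.e. DD = 6 / (2L + 2) >= 0.15 for L <= 15). One
# benign position additionally gives its designated alternative residue the
# consensus weight, so the benign substitution leaves the score unchanged
# (DD = 0).
gen_profile_domain <- function(id, dd_cutoff) {
  L <- sample(6:15, 1)
  consensus <- rletter(L)
  w <- rep(2, L)
  h <- sample(2:(L - 1L), 1)
  w[h] <- 4
  ms <- sum(w)
  stopifnot((w[h] + 2) / ms >= dd_cutoff)  # guaranteed for the default 0.10
  bpos <- sample(setdiff(seq_len(L), h), 1)
  benign_alt <- rletter(1, exclude = consensus[bpos])
  sc <- matrix(-2, nrow = L, ncol = 20, dimnames = list(NULL, AA_ALPHABET))
  for (i in seq_len(L)) sc[i, consensus[i]] <- w[i]
  sc[bpos, benign_alt] <- w[bpos]
  def <- profile_def(id, sc, gap_open = -5, gap_extend = -1,
                     cutoff = ceiling(0.6 * ms))
  list(def = def, kind = "profile", consensus = paste(consensus, collapse = ""),
       benign = list(list(offset = bpos, alts = benign_alt)),
       damaging = list(list(offset = h,
                            alts = setdiff(AA_ALPHABET, consensus[h]))))
}

# Short linear motifs: four exact residues plus one two-letter class keeps
# chance carriage negligible at proteome scale.
gen_motif <- function(id) {
  kinds <- sample(c("exact", "exact", "exact", "exact", "any_of"))
  parts <- character()
  consensus <- character()
  for (kind in kinds) {
    if (kind == "exact") {
      l <- rletter(1)
      parts <- c(parts, l)
      consensus <- c(consensus, l)
    } else if (kind == "any_of") {
      cls <- sort(sample(AA_ALPHABET, 2))
      parts <- c(parts, paste0("[", paste(cls, collapse = ""), "]"))
      consensus <- c(consensus, sample(cls, 1))
    } else {
      l <- rletter(1)
      parts <- c(parts, "x")
      consensus <- c(consensus, l)
    }
  }
  pattern <- paste(parts, collapse = "-")
  list(motif_id = id, pattern = pattern,
       consensus = paste(consensus, collapse = ""))
}

plant <- function(seq_chars, instance, occupied) {
  L <- length(seq_chars)
  w <- nchar(instance)
  if (w > L) return(NULL)
  for (attempt in 1:50) {
    start <- sample(L - w + 1L, 1)
    span <- start:(start + w - 1L)
    if (!any(span %in% occupied)) {
      seq_chars[span] <- strsplit(instance, "", fixed = TRUE)[[1]]
      return(list(seq_chars = seq_chars, start = start, end = start + w - 1L))
    }
  }
  NULL
}

#' Generate a complete synthetic universe with planted ground truth
#'
#' Produces a toy proteome with planted pattern/profile domain and motif
#' instances, missense SNPs stratified outside/inside domains with a planted
#' fraction of domain-altering SNPs, disease labels whose odds are shifted
#' for domain-altering SNPs, a PPI network wired by planted signature-pair
#' binding rules plus uniform noise, and reference pair lists containing the
#' planted rules plus decoys. Planted SNP classes are verified against the
#' actual scanner/classifier during generation (with redraws, up to 100
#' attempts per SNP), so the intended domain-altering SNPs are classified
#' domain-altering by construction.
#'
#' @param cfg A [universe_config()].
#' @return A list of class `dsnp_universe` with elements `proteome`,
#'   `domains`, `motifs`, `snps`, `disease`, `edges`, `reference_pairs`,
#'   `ref_matches` (the reference [scan_proteome()] table), `truth` (planted
#'   ground-truth manifest) and `config`.
#' @export
#' @examples
#' u <- generate_universe(universe_config(seed = 1, n_proteins = 30))
#' u$truth$snps
generate_universe <- function(cfg) {
  stopifnot(inherits(cfg, "universe_config"))
  withr::with_seed(cfg$seed, generate_universe_impl(cfg))
}

generate_universe_impl <- function(cfg) {
  ## --- signature definitions -------------------------------------------
  scan_positions <- cfg$n_proteins * mean(cfg$protein_length)
  meta <- list()
  for (i in seq_len(cfg$n_pattern_domains)) {
    id <- sprintf("PAT%d", i)
    meta[[id]] <- gen_pattern_domain(id, scan_positions)
  }
  for (i in seq_len(cfg$n_profile_domains)) {
    id <- sprintf("PRF%d", i)
    meta[[id]] <- gen_profile_domain(id, cfg$dd_cutoff)
  }
  domains <- structure(lapply(meta, `[[`, "def"), class = "domain_set")
  motif_meta <- lapply(seq_len(cfg$n_motifs),
                       function(i) gen_motif(sprintf("MOT%d", i)))
  motifs <- tibble::tibble(
    motif_id = vapply(motif_meta, `[[`, character(1), "motif_id"),
    pattern = vapply(motif_meta, `[[`, character(1), "pattern")
  )
  motifs$parsed <- purrr::map2(motifs$pattern, motifs$motif_id,
                               ~ parse_pattern(.x, domain_id = .y))

  ## --- proteome with planted instances ---------------------------------
  dom_ids <- names(meta)
  id_width <- max(3L, nchar(as.character(cfg$n_proteins)))
  planted <- list()
  sequences <- character(cfg$n_proteins)
  protein_ids <- sprintf(paste0("PROT%0", id_width, "d"), seq_len(cfg$n_proteins))
  for (i in seq_len(cfg$n_proteins)) {
    L <- sample(cfg$protein_length[1]:cfg$protein_length[2], 1)
    chars <- rletter(L)
    occupied <- integer()
    pid <- protein_ids[i]
    # mutually exclusive planting: at most one planted signature per protein
    to_plant <- character()
    u <- runif(1)
    if (u < cfg$frac_protein_with_domain) {
      to_plant <- sample(dom_ids, 1)
    } else if (cfg$n_motifs > 0L &&
               u < cfg$frac_protein_with_domain + cfg$frac_protein_with_motif) {
      to_plant <- sample(motifs$motif_id, 1)
    }
    for (sig in to_plant) {
      cons <- if (sig %in% dom_ids) meta[[sig]]$consensus else {
        motif_meta[[which(motifs$motif_id == sig)]]$consensus
      }
      res <- plant(chars, cons, occupied)
      if (is.null(res)) next
      chars <- res$seq_chars
      occupied <- c(occupied, res$start:res$end)
      planted[[length(planted) + 1L]] <- tibble::tibble(
        protein_id = pid, signature_id = sig,
        kind = if (sig %in% dom_ids) meta[[sig]]$kind else "motif",
        start = res$start, end = res$end
      )
    }
    sequences[i] <- paste(chars, collapse = "")
  }
  proteome <- tibble::tibble(protein_id = protein_ids,
                             gene_symbol = paste0("G", protein_ids),
                             sequence = sequences)
  planted <- if (length(planted) > 0L) dplyr::bind_rows(planted) else {
    tibble::tibble(protein_id = character(), signature_id = character(),
                   kind = character(), start = integer(), end = integer())
  }

  ref_matches <- scan_proteome(domains, proteome)

  ## --- SNPs -------------------------------------------------------------
  # conditional in-domain probability so the *overall* in-domain fraction
  # matches frac_snp_in_domain despite not every protein carrying a domain
  p_cond <- min(1, cfg$frac_snp_in_domain / max(cfg$frac_protein_with_domain, 1e-9))
  v_snp_id <- v_pid <- v_ref <- v_alt <- v_class <- v_mech <- v_dom <- character()
  v_pos <- integer()
  v_verified <- logical()
  serial <- 0L
  matches_by_protein <- split(ref_matches, ref_matches$protein_id)
  no_match <- ref_matches[0, , drop = FALSE]
  planted_by_protein <- split(
    planted[planted$kind != "motif", , drop = FALSE],
    planted$protein_id[planted$kind != "motif"]
  )
  for (i in seq_len(cfg$n_proteins)) {
    pid <- protein_ids[i]
    s <- sequences[i]
    rm <- matches_by_protein[[pid]] %||% no_match
    spans <- planted_by_protein[[pid]]
    n_spans <- if (is.null(spans)) 0L else nrow(spans)
    n_snp <- rpois(1, cfg$snps_per_protein)
    for (j in seq_len(n_snp)) {
      in_domain <- n_spans > 0L && runif(1) < p_cond
      damaging <- in_domain && runif(1) < cfg$frac_da_given_domain
      serial <- serial + 1L
      drawn <- draw_snp(s, rm, spans, meta, domains, in_domain, damaging,
                        cfg$dd_cutoff)
      if (is.null(drawn)) next
      v_snp_id <- c(v_snp_id, sprintf("rs%06d", serial))
      v_pid <- c(v_pid, pid)
      v_pos <- c(v_pos, drawn$position)
      v_ref <- c(v_ref, drawn$ref_aa)
      v_alt <- c(v_alt, drawn$alt_aa)
      v_class <- c(v_class, drawn$intended_class)
      v_mech <- c(v_mech, drawn$mechanism)
      v_dom <- c(v_dom, drawn$domain_id)
      v_verified <- c(v_verified, drawn$verified)
    }
  }
  snps <- tibble::tibble(snp_id = v_snp_id, protein_id = v_pid,
                         position = v_pos, ref_aa = v_ref, alt_aa = v_alt)
  snp_truth <- tibble::tibble(snp_id = v_snp_id, protein_id = v_pid,
                              intended_class = v_class, mechanism = v_mech,
                              domain_id = v_dom, verified = v_verified)

  ## --- disease labels ---------------------------------------------------
  is_da <- snp_truth$intended_class == "da_snp"
  p_dis <- plogis(qlogis(cfg$disease_base_rate) +
                    log(cfg$disease_odds_ratio_da) * is_da)
  diseased <- runif(nrow(snps)) < p_dis
  disease_snps <- snps$snp_id[diseased]
  disease <- if (length(disease_snps) > 0L) {
    snp_level <- tibble::tibble(
      id_type = "snp", id = disease_snps,
      disorder = paste0("disorder_", sample(20L, length(disease_snps), replace = TRUE))
    )
    prot_level <- tibble::tibble(
      id_type = "protein",
      id = sort(unique(snps$protein_id[diseased])),
      disorder = "disorder_protein_level"
    )
    dplyr::bind_rows(snp_level, prot_level)
  } else {
    tibble::tibble(id_type = character(), id = character(), disorder = character())
  }
  disease$orphan <- FALSE

  ## --- binding rules and PPI edges --------------------------------------
  sig_ids <- c(dom_ids, motifs$motif_id)
  carriers <- split(planted$protein_id, planted$signature_id)
  rules <- gen_rules(cfg, dom_ids, motifs$motif_id, carriers)
  net <- gen_edges(cfg, rules, carriers, protein_ids)

  ## --- reference pair lists ---------------------------------------------
  reference_pairs <- gen_reference_pairs(cfg, rules, dom_ids, motifs$motif_id)

  truth <- list(
    planted_spans = planted,
    snps = snp_truth,
    rules = rules,
    edges = net$edge_truth,
    diseased_snp_ids = disease_snps,
    config = unclass(cfg)
  )
  structure(
    list(proteome = proteome, domains = domains, motifs = motifs, snps = snps,
         disease = disease, edges = net$edges,
         reference_pairs = reference_pairs, ref_matches = ref_matches,
         truth = truth, config = cfg),
    class = "dsnp_universe"
  )
}

# Draw one SNP of the requested stratum and verify its realized class with
# the actual classifier; redraw up to 100 times on mismatch.
draw_snp <- function(s, rm, spans, meta, domains, in_domain, damaging,
                     dd_cutoff) {
  L <- nchar(s)
  want <- if (!in_domain) "outside" else if (damaging) "da_snp" else "d_snp"
  for (attempt in 1:100) {
    if (!in_domain) {
      free <- setdiff(seq_len(L), unlist(purrr::map2(rm$start, rm$end, seq)))
      if (length(free) == 0L) return(NULL)
      pos <- free[sample.int(length(free), 1)]
      ref <- substr(s, pos, pos)
      alt <- rletter(1, exclude = ref)
      dom_id <- NA_character_
      mech <- "none"
    } else {
      k <- sample.int(nrow(spans), 1)
      dom_id <- spans$signature_id[k]
      m <- meta[[dom_id]]
      pool <- if (damaging) m$damaging else m$benign
      if (length(pool) == 0L) return(NULL)
      site <- pool[[sample.int(length(pool), 1)]]
      pos <- spans$start[k] + site$offset - 1L
      ref <- substr(s, pos, pos)
      alts <- setdiff(site$alts, ref)
      if (length(alts) == 0L) next
      alt <- alts[sample.int(length(alts), 1)]
      mech <- if (!damaging) "none" else if (m$kind == "pattern") {
        "pattern_loss"
      } else {
        "profile_distortion"
      }
    }
    snp <- list(snp_id = "tmp", protein_id = "tmp", position = pos,
                ref_aa = ref, alt_aa = alt)
    cls <- classify_snp(snp, s, rm, domains, dd_cutoff = dd_cutoff)
    realized <- if (any(cls$status == "da_snp")) "da_snp" else {
      if (any(cls$status == "d_snp")) "d_snp" else "outside"
    }
    if (realized == want) {
      return(list(position = pos, ref_aa = ref, alt_aa = alt,
                  intended_class = want, mechanism = mech,
                  domain_id = dom_id, verified = TRUE))
    }
  }
  if (want == "da_snp") return(NULL)  # never emit an unverified damaging SNP
  list(position = pos, ref_aa = ref, alt_aa = alt, intended_class = want,
       mechanism = mech, domain_id = dom_id, verified = FALSE)
}

gen_rules <- function(cfg, dom_ids, motif_ids, carriers) {
  if (cfg$n_binding_rules == 0L) {
    return(tibble::tibble(rule_id = character(), domain_id = character(),
                          signature_id = character(), kind = character()))
  }
  # only signatures with at least 2 carriers can wire edges
  usable_dom <- dom_ids[vapply(dom_ids, function(d) length(carriers[[d]] %||% character()) >= 2L, logical(1))]
  usable_sig <- c(usable_dom,
                  motif_ids[vapply(motif_ids, function(m) length(carriers[[m]] %||% character()) >= 2L, logical(1))])
  rules <- list()
  seen <- character()
  guard <- 0L
  while (length(rules) < cfg$n_binding_rules && guard < 1000L) {
    guard <- guard + 1L
    d <- sample(usable_dom, 1)
    s <- sample(setdiff(usable_sig, d), 1)
    key <- paste(d, s, sep = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    rules[[length(rules) + 1L]] <- tibble::tibble(
      rule_id = sprintf("RULE%d", length(rules) + 1L),
      domain_id = d, signature_id = s,
      kind = if (s %in% dom_ids) "domain_domain" else "domain_motif"
    )
  }
  dplyr::bind_rows(rules)
}

gen_edges <- function(cfg, rules, carriers, protein_ids) {
  target <- round(cfg$edge_density * cfg$n_proteins)
  empty <- list(
    edges = tibble::tibble(protein_a = character(), protein_b = character()),
    edge_truth = tibble::tibble(protein_a = character(), protein_b = character(),
                                rule_id = character())
  )
  if (target == 0L) return(empty)
  n_rule_edges <- round(cfg$rule_fidelity * target)
  pool <- list()
  for (r in seq_len(nrow(rules))) {
    hosts <- carriers[[rules$domain_id[r]]] %||% character()
    partners <- carriers[[rules$signature_id[r]]] %||% character()
    if (length(hosts) == 0L || length(partners) == 0L) next
    grid <- expand.grid(a = hosts, b = partners, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    if (nrow(grid) == 0L) next
    pool[[length(pool) + 1L]] <- tibble::tibble(
      protein_a = pmin(grid$a, grid$b), protein_b = pmax(grid$a, grid$b),
      rule_id = rules$rule_id[r]
    )
  }
  rule_edges <- if (length(pool) > 0L) {
    pool <- dplyr::bind_rows(pool) |>
      dplyr::distinct(.data$protein_a, .data$protein_b, .keep_all = TRUE)
    pool[sample.int(nrow(pool), min(n_rule_edges, nrow(pool))), , drop = FALSE]
  } else {
    empty$edge_truth
  }
  # noise volume follows (1 - fidelity) directly: an exhausted rule pool
  # shrinks the network rather than diluting it with extra noise
  n_noise <- round((1 - cfg$rule_fidelity) * target)
  existing <- paste(rule_edges$protein_a, rule_edges$protein_b, sep = "\r")
  noise <- list()
  guard <- 0L
  while (length(noise) < n_noise && guard < 50L * max(n_noise, 1L)) {
    guard <- guard + 1L
    ab <- sample(protein_ids, 2)
    a <- min(ab); b <- max(ab)
    key <- paste(a, b, sep = "\r")
    if (key %in% existing) next
    existing <- c(existing, key)
    noise[[length(noise) + 1L]] <- tibble::tibble(protein_a = a, protein_b = b,
                                                  rule_id = "noise")
  }
  edge_truth <- dplyr::bind_rows(rule_edges, dplyr::bind_rows(noise)) |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
  list(edges = edge_truth[, c("protein_a", "protein_b")], edge_truth = edge_truth)
}

gen_reference_pairs <- function(cfg, rules, dom_ids, motif_ids) {
  keep <- rules[runif(nrow(rules)) < cfg$frac_rules_in_reference, , drop = FALSE]
  planted <- tibble::tibble(kind = keep$kind, sig_a = keep$domain_id,
                            sig_b = keep$signature_id)
  rule_keys <- paste(rules$domain_id, rules$signature_id, sep = "\r")
  decoys <- list()
  guard <- 0L
  while (length(decoys) < cfg$n_decoy_pairs && guard < 1000L) {
    guard <- guard + 1L
    d <- sample(dom_ids, 1)
    s <- sample(setdiff(c(dom_ids, motif_ids), d), 1)
    if (paste(d, s, sep = "\r") %in% rule_keys) next
    decoys[[length(decoys) + 1L]] <- tibble::tibble(
      kind = if (s %in% dom_ids) "domain_domain" else "domain_motif",
      sig_a = d, sig_b = s
    )
  }
  normalize_pairs(dplyr::bind_rows(planted, dplyr::bind_rows(decoys)))
}

#' @export
print.dsnp_universe <- function(x, ...) {
  cat("<dsnp_universe> seed=", x$config$seed, ": ",
      nrow(x$proteome), " proteins, ", length(x$domains), " domains, ",
      nrow(x$snps), " SNPs, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Expected downstream counts for a generated universe
#'
#' Reads the ground-truth manifest and returns the intended counts every
#' downstream stage should reproduce: exact for constructed quantities,
#' with a +-3-sd binomial band for the stochastic disease counts.
#'
#' @param universe A `dsnp_universe`.
#' @return A tibble with columns `quantity`, `value`, `lower`, `upper`,
#'   `exact`.
#' @export
expected_counts <- function(universe) {
  tr <- universe$truth
  cfg <- universe$config
  n_snps <- nrow(universe$snps)
  n_da <- sum(tr$snps$intended_class == "da_snp")
  n_in <- sum(tr$snps$intended_class != "outside")
  p0 <- cfg$disease_base_rate
  p1 <- plogis(qlogis(p0) + log(cfg$disease_odds_ratio_da))
  mu_dis <- (n_snps - n_da) * p0 + n_da * p1
  sd_dis <- sqrt((n_snps - n_da) * p0 * (1 - p0) + n_da * p1 * (1 - p1))
  tibble::tibble(
    quantity = c("n_snps", "n_d_snp_intended", "n_da_snp_intended",
                 "n_rules", "n_edges", "n_rule_edges", "n_diseased_snps"),
    value = c(n_snps, n_in, n_da, nrow(tr$rules), nrow(universe$edges),
              sum(tr$edges$rule_id != "noise"),
              length(tr$diseased_snp_ids)),
    lower = c(NA, NA, NA, NA, NA, NA, mu_dis - 3 * sd_dis),
    upper = c(NA, NA, NA, NA, NA, NA, mu_dis + 3 * sd_dis),
    exact = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' Benchmark recovered signature pairs against the planted binding rules
#'
#' Compares the enriched pairs of a [score_pairs()] result with a universe's
#' planted rules. Domain-domain rules are matched unordered (either
#' direction of an undirected co-occurrence recovers the rule, and a
#' reversed detection is not a false positive); domain-motif rules are
#' matched as (domain, motif).
#'
#' @param universe A `dsnp_universe`.
#' @param scores A `signature_pairs` tibble from [score_pairs()].
#' @return A one-row tibble: `n_rules`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`.
#' @export
rule_recovery <- function(universe, scores) {
  rules <- universe$truth$rules
  rule_key <- function(a, b, kind) {
    ifelse(kind == "domain_domain",
           paste(pmin(a, b), pmax(a, b), sep = "\r"),
           paste(a, b, sep = "\r"))
  }
  planted <- unique(rule_key(rules$domain_id, rules$signature_id, rules$kind))
  det <- scores[scores$enriched, , drop = FALSE]
  det_kind <- ifelse(det$signature_kind == "domain", "domain_domain", "domain_motif")
  detected <- unique(rule_key(det$domain_id, det$signature_id, det_kind))
  tp <- sum(detected %in% planted)
  fp <- sum(!detected %in% planted)
  fn <- sum(!planted %in% detected)
  tibble::tibble(
    n_rules = length(planted), tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  )
}

#' Write a generated universe to disk
#'
#' Writes every input file of the pipeline (`proteome.fasta`, `snps.tsv`,
#' `edges.tsv`, `disease.tsv`, `pairs.tsv`, `motifs.tsv`, `domains.txt`)
#' plus the ground-truth manifest `truth.json` into `dir`.
#'
#' @param universe A `dsnp_universe`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_proteome(universe$proteome, file.path(dir, "proteome.fasta"))
  write_snps(universe$snps, file.path(dir, "snps.tsv"))
  write_ppi_edges(universe$edges, file.path(dir, "edges.tsv"))
  write_disease_annotations(universe$disease, file.path(dir, "disease.tsv"))
  write_reference_pairs(universe$reference_pairs, file.path(dir, "pairs.tsv"))
  write_motifs(universe$motifs, file.path(dir, "motifs.tsv"))
  write_domains(universe$domains, file.path(dir, "domains.txt"))
  jsonlite::write_json(
    list(
      planted_spans = universe$truth$planted_spans,
      snps = universe$truth$snps,
      rules = universe$truth$rules,
      edges = universe$truth$edges,
      diseased_snp_ids = universe$truth$diseased_snp_ids,
      config = universe$truth$config
    ),
    file.path(dir, "truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
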