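# codon table (no stops) for reverse translation
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], gc[gc != "*"])
}

# mutate an amino-acid string: i.i.d. per-site substitution at `rate`,
# uniform over the 19 alternatives (uses the current RNG stream)
mutate_protein <- function(residues, rate) {
  ch <- split_chars(residues)
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(r) {
      sample(setdiff(AA_CHARS, r), 1L)
    }, character(1))
  }
  paste(ch, collapse = "")
}

mutate_dna <- function(residues, rate) {
  ch <- split_chars(residues)
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(r) {
      sample(setdiff(DNA_CHARS[1:4], r), 1L)
    }, character(1))
  }
  paste(ch, collapse = "")
}

#' Sample diverged repeat units from a consensus
#'
#' Each unit is the consensus with independent per-site substitutions at
#' rate \code{divergence}, uniform over the alternative residues. The
#' inverse operation of consensus calling: majority voting over enough
#' units recovers the generating consensus.
#'
#' @param consensus Consensus string or a \code{consensus_profile}.
#' @param n_units Number of units.
#' @param divergence Per-site substitution probability in [0, 1).
#' @param seed RNG seed (required).
#' @return Character vector of unit strings.
#' @export
sample_repeat_units <- function(consensus, n_units, divergence, seed) {
  if (inherits(consensus, "consensus_profile")) {
    consensus <- consensus$consensus
  }
  stopifnot(is.character(consensus), nchar(consensus) >= 1L,
            divergence >= 0, divergence < 1)
  if (missing(seed) || is.null(seed)) stop_plastex("seed is required")
  with_seed(seed, vapply(seq_len(n_units), function(i) {
    mutate_protein(consensus, divergence)
  }, character(1)))
}

#' Specification of a synthetic multi-exon locus
#'
#' Defaults emulate a compact multi-exon coding locus with one long
#' tandem-repeat exon of 13-residue-period units: eight exons whose lengths
#' are all divisible by 3 (so every exon is skippable in frame), a
#' 195-nt repeat exon of five units diverged 10\% from the canonical
#' 13-residue consensus, and introns of 60-200 nt with canonical GT-AG
#' flanks.
#'
#' @param exon_lengths Exon lengths in nt (default
#'   \code{c(120, 90, 75, 195, 87, 90, 60, 120)}).
#' @param intron_length_range Intron length range in nt (min >= 30).
#' @param repeat_exon List: \code{exon_index}, \code{unit_consensus},
#'   \code{n_units}, \code{divergence}; or \code{NULL}.
#' @param duplication_cluster Optional list: \code{template_exon},
#'   \code{n_copies}, \code{divergence}.
#' @param flank Flanking DNA length on each side (default 100 nt).
#' @param seed RNG seed (required, never defaulted silently).
#' @return Object of class \code{locus_spec}.
#' @export
locus_spec <- function(exon_lengths = c(120L, 90L, 75L, 195L, 87L, 90L,
                                        60L, 120L),
                       intron_length_range = c(60L, 200L),
                       repeat_exon = list(exon_index = 4L,
                                          unit_consensus = "PSITKVTRVIEGE",
                                          n_units = 5L, divergence = 0.1),
                       duplication_cluster = NULL, flank = 100L, seed) {
  if (missing(seed) || is.null(seed)) stop_plastex("seed is required")
  stopifnot(all(exon_lengths >= 3L), length(intron_length_range) == 2L,
            intron_length_range[1] >= 30L,
            intron_length_range[1] <= intron_length_range[2])
  if (sum(exon_lengths) %% 3L != 0L) {
    stop_plastex("total exon length must be divisible by 3")
  }
  if (!is.null(repeat_exon)) {
    idx <- repeat_exon$exon_index
    stopifnot(idx >= 1L, idx <= length(exon_lengths))
    needed <- repeat_exon$n_units * nchar(repeat_exon$unit_consensus) * 3L
    if (exon_lengths[idx] != needed) {
      stop_plastex("repeat exon length (", exon_lengths[idx],
                   ") must equal n_units * unit length * 3 = ", needed)
    }
  }
  if (!is.null(duplication_cluster)) {
    stopifnot(duplication_cluster$template_exon >= 1L,
              duplication_cluster$template_exon <= length(exon_lengths),
              duplication_cluster$n_copies >= 1L)
    if (exon_lengths[duplication_cluster$template_exon] %% 3L != 0L) {
      stop_plastex("duplication template exon must be frame-preserving")
    }
  }
  structure(list(exon_lengths = as.integer(exon_lengths),
                 intron_length_range = as.integer(intron_length_range),
                 repeat_exon = repeat_exon,
                 duplication_cluster = duplication_cluster,
                 flank = as.integer(flank), seed = seed),
            class = "locus_spec")
}

#' Simulate a multi-exon coding locus
#'
#' Coding exons are sampled stop-free by construction (the protein is
#' generated first and reverse-translated with uniformly sampled
#' synonymous codons); introns are uniform-random DNA with forced
#' GT...AG flanks; the repeat exon is built from
#' \code{\link{sample_repeat_units}}; an optional duplication cluster
#' inserts diverged copies of a template exon (with independent introns)
#' immediately downstream of it. Byte-reproducible given the spec and its
#' seed.
#'
#' @param spec A \code{\link{locus_spec}}.
#' @return List: \code{genomic} (DNA \code{\link{bio_seq}}), \code{model}
#'   (truth \code{\link{gene_model}}, coding-complete), \code{protein}
#'   (truth protein \code{\link{bio_seq}}), \code{spec}.
#' @export
simulate_locus <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  with_seed(spec$seed, {
    ct <- codon_table()
    rev_translate <- function(aa) {
      paste(vapply(split_chars(aa), function(r) {
        cods <- ct[[r]]
        cods[sample.int(length(cods), 1L)]
      }, character(1)), collapse = "")
    }
    n0 <- length(spec$exon_lengths)
    lens <- spec$exon_lengths
    total_aa <- sum(lens) %/% 3L
    prot <- sample(AA_CHARS, total_aa, replace = TRUE, prob = UNIPROT_BG)
    cum_nt <- c(0L, cumsum(lens))
    if (!is.null(spec$repeat_exon)) {
      rx <- spec$repeat_exon
      units <- vapply(seq_len(rx$n_units), function(k) {
        mutate_protein(rx$unit_consensus, rx$divergence)
      }, character(1))
      rep_aa <- split_chars(paste(units, collapse = ""))
      aa_from <- cum_nt[rx$exon_index] %/% 3L + 1L
      prot[seq(aa_from, length.out = length(rep_aa))] <- rep_aa
    }
    cds <- rev_translate(paste(prot, collapse = ""))
    # cut the CDS at the exact exon boundaries (frame-breaking lengths
    # split codons across introns, as in real genes)
    nt_pieces <- substring(cds, cum_nt[-length(cum_nt)] + 1L,
                           cum_nt[-1L])
    labels <- as.character(seq_len(n0))
    if (!is.null(spec$duplication_cluster)) {
      dc <- spec$duplication_cluster
      t_idx <- dc$template_exon
      if (any(lens %% 3L != 0L)) {
        stop_plastex("duplication clusters require frame-preserving exons")
      }
      aa_t_from <- cum_nt[t_idx] %/% 3L + 1L
      aa_t_to <- cum_nt[t_idx + 1L] %/% 3L
      tmpl_aa <- paste(prot[aa_t_from:aa_t_to], collapse = "")
      copies <- vapply(seq_len(dc$n_copies), function(k) {
        rev_translate(mutate_protein(tmpl_aa, dc$divergence))
      }, character(1))
      nt_pieces <- append(nt_pieces, copies, after = t_idx)
      copy_labels <- paste0(labels[t_idx], LETTERS[seq_len(dc$n_copies)])
      labels <- append(labels, copy_labels, after = t_idx)
    }
    n <- length(nt_pieces)
    intron_len <- sample(spec$intron_length_range[1]:
                           spec$intron_length_range[2], n - 1L,
                         replace = TRUE)
    introns <- vapply(intron_len, function(L) {
      s <- paste(sample(DNA_CHARS[1:4], L, replace = TRUE), collapse = "")
      paste0("GT", substr(s, 3L, L - 2L), "AG")
    }, character(1))
    flank5 <- paste(sample(DNA_CHARS[1:4], spec$flank, replace = TRUE),
                    collapse = "")
    flank3 <- paste(sample(DNA_CHARS[1:4], spec$flank, replace = TRUE),
                    collapse = "")
    pos <- spec$flank
    starts <- integer(n); ends <- integer(n)
    parts <- character(0)
    for (i in seq_len(n)) {
      starts[i] <- pos
      ends[i] <- pos + nchar(nt_pieces[i])
      parts <- c(parts, nt_pieces[i])
      pos <- ends[i]
      if (i < n) {
        parts <- c(parts, introns[i])
        pos <- pos + nchar(introns[i])
      }
    }
    genomic <- bio_seq(paste0(flank5, paste(parts, collapse = ""), flank3),
                       id = "synthetic_locus", alphabet = "DNA")
    cum <- c(0L, cumsum(nchar(nt_pieces)))
    exons <- lapply(seq_len(n), function(i) {
      fl <- exon_flanks(genomic, starts[i], ends[i], "+")
      exon_model(starts[i], ends[i], "+", phase = cum[i] %% 3L,
                 donor = if (i < n) fl$donor else "",
                 acceptor = if (i > 1L) fl$acceptor else "",
                 label = labels[i])
    })
    model <- gene_model(genomic$id, exons, "+", coding_complete = TRUE,
                        contig_length = nchar(genomic$residues))
    protein <- translate_dna(bio_seq(paste(nt_pieces, collapse = ""),
                                     alphabet = "DNA"))
    protein$id <- "synthetic_protein"
    list(genomic = genomic, model = model, protein = protein, spec = spec)
  })
}

#' Splicing specification for transcript simulation
#'
#' @param inclusion_prob Per-exon inclusion probabilities in [0, 1]
#'   (length = exon count of the model).
#' @param constitutive Logical per exon; constitutive exons must have
#'   inclusion probability 1 (enforced).
#' @param n_transcripts Number of transcripts to simulate.
#' @param truncation_prob Probability that a transcript is EST-style
#'   truncated at either end (each end independently).
#' @param truncation_len_range Clip length range in nt.
#' @return Object of class \code{splice_spec}.
#' @export
splice_spec <- function(inclusion_prob, constitutive = NULL,
                        n_transcripts = 100L, truncation_prob = 0,
                        truncation_len_range = c(10L, 100L)) {
  stopifnot(all(inclusion_prob >= 0), all(inclusion_prob <= 1))
  if (is.null(constitutive)) constitutive <- inclusion_prob >= 1
  if (any(constitutive & inclusion_prob < 1)) {
    stop_plastex("constitutive exons must have inclusion probability 1")
  }
  structure(list(inclusion_prob = inclusion_prob,
                 constitutive = constitutive,
                 n_transcripts = as.integer(n_transcripts),
                 truncation_prob = truncation_prob,
                 truncation_len_range = as.integer(truncation_len_range)),
            class = "splice_spec")
}

#' Simulate spliced transcripts with cassette-exon sampling
#'
#' Each transcript includes each exon independently with its inclusion
#' probability (constitutive exons always). Combinations whose excluded
#' length is not divisible by 3 are flagged frame-breaking in the truth
#' table. EST-style truncation is applied last.
#'
#' @param model Coding-complete \code{\link{gene_model}}.
#' @param genomic DNA \code{\link{bio_seq}}.
#' @param splice A \code{\link{splice_spec}}.
#' @param seed RNG seed (required).
#' @return List: \code{transcripts} (list of DNA \code{bio_seq}),
#'   \code{truth} (data frame: transcript, one inclusion column per exon
#'   label, \code{frame_breaking}, \code{clip5}, \code{clip3}).
#' @export
simulate_transcripts <- function(model, genomic, splice, seed) {
  stopifnot(inherits(model, "gene_model"), inherits(splice, "splice_spec"))
  if (missing(seed) || is.null(seed)) stop_plastex("seed is required")
  n_ex <- length(model$exons)
  stopifnot(length(splice$inclusion_prob) == n_ex)
  exon_seqs <- vapply(model$exons, function(e) {
    res <- if (model$strand == "+") genomic$residues
           else reverse_complement(genomic)$residues
    glen <- nchar(genomic$residues)
    s <- if (model$strand == "+") e$start else glen - e$end
    substr(res, s + 1L, s + exon_length(e))
  }, character(1))
  labels <- vapply(model$exons, `[[`, "", "label")
  with_seed(seed, {
    rows <- vector("list", splice$n_transcripts)
    transcripts <- vector("list", splice$n_transcripts)
    for (t in seq_len(splice$n_transcripts)) {
      inc <- runif(n_ex) < splice$inclusion_prob | splice$constitutive
      excluded_len <- sum(nchar(exon_seqs)[!inc])
      seq <- paste(exon_seqs[inc], collapse = "")
      clip5 <- 0L; clip3 <- 0L
      if (splice$truncation_prob > 0) {
        rng <- splice$truncation_len_range
        if (runif(1) < splice$truncation_prob) {
          clip5 <- min(sample(rng[1]:rng[2], 1L), nchar(seq) - 1L)
        }
        if (runif(1) < splice$truncation_prob) {
          clip3 <- min(sample(rng[1]:rng[2], 1L), nchar(seq) - 1L - clip5)
        }
        seq <- substr(seq, clip5 + 1L, nchar(seq) - clip3)
      }
      transcripts[[t]] <- bio_seq(seq, id = sprintf("transcript%03d", t),
                                  alphabet = "DNA")
      row <- as.list(as.integer(inc))
      names(row) <- paste0("exon_", labels)
      rows[[t]] <- data.frame(transcript = sprintf("transcript%03d", t),
                              row,
                              frame_breaking = excluded_len %% 3L != 0L,
                              clip5 = clip5, clip3 = clip3,
                              check.names = FALSE)
    }
    list(transcripts = transcripts, truth = do.call(rbind, rows))
  })
}

#' Evolve a protein along a tree under a two-rate regional regime
#'
#' Per branch and region, a Poisson number of substitutions
#' (\code{rate * branch length * region size}) is applied at uniform
#' positions, each substitution uniform over the 19 alternative residues.
#' This emulates a conserved region (A) next to a fast-evolving one (B)
#' along a known phylogeny. Deterministic per seed.
#'
#' @param root Protein \code{\link{bio_seq}} at the root.
#' @param tree Rooted \pkg{ape} \code{phylo} with branch lengths (an
#'   unrooted tree is rooted at its first tip).
#' @param region_A,region_B Disjoint position index vectors partitioning
#'   the sequence.
#' @param rate_A,rate_B Per-site substitution rates (per unit branch
#'   length).
#' @param seed RNG seed (required).
#' @return Named list of leaf \code{bio_seq}s (tip label order).
#' @export
evolve_two_rate <- function(root, tree, region_A, region_B, rate_A, rate_B,
                            seed) {
  stopifnot(inherits(root, "bio_seq"), root$alphabet == "PROTEIN",
            inherits(tree, "phylo"), rate_A >= 0, rate_B >= 0)
  if (missing(seed) || is.null(seed)) stop_plastex("seed is required")
  L <- nchar(root$residues)
  if (!setequal(c(region_A, region_B), seq_len(L)) ||
      length(intersect(region_A, region_B))) {
    stop_plastex("regions must partition the sequence positions")
  }
  if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[1],
                      resolve.root = TRUE)
  }
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  with_seed(seed, {
    seqs <- vector("list", max(tree$edge))
    seqs[[root_node]] <- split_chars(root$residues)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[k, 1]; child <- ord$edge[k, 2]
      bl <- ord$edge.length[k]
      ch <- seqs[[parent]]
      for (reg in list(list(idx = region_A, rate = rate_A),
                       list(idx = region_B, rate = rate_B))) {
        n_sub <- rpois(1L, reg$rate * bl * length(reg$idx))
        if (n_sub > 0L) {
          pos <- sample(reg$idx, n_sub, replace = TRUE)
          for (p in pos) ch[p] <- sample(setdiff(AA_CHARS, ch[p]), 1L)
        }
      }
      seqs[[child]] <- ch
    }
    out <- lapply(seq_len(n_tip), function(i) {
      bio_seq(paste(seqs[[i]], collapse = ""), id = tree$tip.label[i],
              alphabet = "PROTEIN")
    })
    names(out) <- tree$tip.label
    out
  })
}

#' Synthetic stand-in for the six-locus teleost repeat-region set
#'
#' Builds six protein repeat regions with the canonical per-locus unit
#' counts of the teleost repeat census (6, 13, 7, 5, 8, and 6 units; 45
#' in total), each unit diverged from the 13-residue consensus, with short
#' random flanking residues. This is a synthetic emulation used where the
#' curated sequence listing is not redistributed; unit counts and the
#' consensus are the generating truth.
#'
#' @param seed RNG seed (required).
#' @param divergence Per-site unit divergence (default 0.15, a
#'   well-conserved repeat).
#' @param unit_counts Named integer vector of per-locus unit counts.
#' @param consensus Generating unit consensus.
#' @param flank Number of random flanking residues each side (default 3).
#' @return Named list of protein \code{\link{bio_seq}}s.
#' @export
synthetic_teleost_repeat_set <- function(seed, divergence = 0.15,
                                         unit_counts = c(Dr_locus1 = 6L,
                                                         Dr_locus2 = 13L,
                                                         Ga_locus1 = 7L,
                                                         Ga_locus2 = 5L,
                                                         Tn_locus2 = 8L,
                                                         Tr_locus2 = 6L),
                                         consensus = "PSITKVTRVIEGE",
                                         flank = 3L) {
  if (missing(seed) || is.null(seed)) stop_plastex("seed is required")
  with_seed(seed, {
    out <- lapply(seq_along(unit_counts), function(i) {
      units <- vapply(seq_len(unit_counts[i]), function(k) {
        mutate_protein(consensus, divergence)
      }, character(1))
      fl <- function() if (flank > 0L) {
        paste(sample(AA_CHARS, flank, replace = TRUE, prob = UNIPROT_BG),
              collapse = "")
      } else ""
      bio_seq(paste0(fl(), paste(units, collapse = ""), fl()),
              id = names(unit_counts)[i], alphabet = "PROTEIN")
    })
    names(out) <- names(unit_counts)
    out
  })
}

# substitute exactly k positions (uniform alternatives) — models a homolog
# at a fixed evolutionary distance rather than i.i.d. noise
mutate_protein_fixed <- function(residues, k) {
  ch <- split_chars(residues)
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(AA_CHARS, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Duplet-rule benchmark: single- vs two-unit profile searches
#'
#' Per replicate seed, builds (i) a profile from four repeat units at 20\%
#' divergence from the consensus and (ii) its two-unit (duplet) version
#' from consecutive unit pairs; scans a database of one true target — a
#' distant homolog whose repeat array descends from an ancestor unit with
#' exactly \code{n_anc_subs} of 13 positions substituted (about 54\%
#' identity, mammalian-range divergence) expanded into
#' \code{n_target_units} nearly identical copies between random flanks —
#' plus ten generic-repeat decoys (tandem low-complexity and myosin-like
#' heptad proteins of \code{decoy_length} residues). Reports whether each
#' profile ranks the true target first. The expected pattern is the duplet
#' rule: the two-unit profile always ranks the true homolog first, while
#' the single-unit profile is overtaken by generic repeats in some
#' replicates.
#'
#' @param seeds Replicate seeds (default 1:10).
#' @param consensus Repeat unit consensus.
#' @param n_anc_subs Substitutions in the target's ancestor unit
#'   (default 6 of 13).
#' @param n_target_units Units in the target's repeat array (default 8).
#' @param decoy_length Decoy protein length (default 2000, myosin-scale).
#' @param n_decoys Number of decoys (default 10).
#' @return Data frame: \code{seed}, \code{one_unit_top},
#'   \code{two_unit_top}, and the true/decoy best scores for both
#'   profiles.
#' @export
duplet_rule_experiment <- function(seeds = 1:10,
                                   consensus = "PSITKVTRVIEGE",
                                   n_anc_subs = 6L, n_target_units = 8L,
                                   decoy_length = 2000L, n_decoys = 10L) {
  rows <- lapply(seeds, function(sd) {
    r <- with_seed(1000 + sd, {
      units <- vapply(1:4, function(i) mutate_protein(consensus, 0.2),
                      character(1))
      anc <- mutate_protein_fixed(consensus, n_anc_subs)
      tunits <- vapply(seq_len(n_target_units), function(i) {
        mutate_protein(anc, 0.03)
      }, character(1))
      bg <- function(n) paste(sample(AA_CHARS, n, TRUE, prob = UNIPROT_BG),
                              collapse = "")
      tgt <- bio_seq(paste0(bg(150L), paste(tunits, collapse = ""),
                            bg(150L)), id = "true_target")
      list(units = units, tgt = tgt)
    })
    decoys <- sample_decoy_proteins(n_decoys, length = decoy_length,
                                    seed = 2000 + sd)
    db <- c(list(r$tgt), decoys)
    u <- r$units
    p1 <- build_profile(u, n_units_in_query = 1L)
    p2 <- build_profile(c(paste0(u[1], u[2]), paste0(u[2], u[3]),
                          paste0(u[3], u[4]), paste0(u[4], u[1])),
                        n_units_in_query = 2L)
    h1 <- suppressWarnings(scan_profile(p1, db))
    h2 <- scan_profile(p2, db)
    true1 <- h1$score[h1$target_id == "true_target"]
    dec1 <- max(h1$score[h1$target_id != "true_target"])
    true2 <- h2$score[h2$target_id == "true_target"]
    dec2 <- max(h2$score[h2$target_id != "true_target"])
    data.frame(seed = sd, one_unit_top = true1 > dec1,
               two_unit_top = true2 > dec2, true_score_1 = true1,
               decoy_score_1 = dec1, true_score_2 = true2,
               decoy_score_2 = dec2)
  })
  do.call(rbind, rows)
}

#' Generic-repeat decoy proteins for profile-search benchmarking
#'
#' Emits tandem low-complexity proteins and coiled-coil-like heptad
#' textures — the kind of generically repetitive sequence that a
#' single-repeat-unit query spuriously matches.
#'
#' @param n Number of decoys.
#' @param length Decoy length in residues (default 400).
#' @param seed RNG seed (required).
#' @return List of protein \code{\link{bio_seq}}s, ids
#'   \code{decoy_lowcomp*} / \code{decoy_heptad*}.
#' @export
sample_decoy_proteins <- function(n, length = 400L, seed) {
  if (missing(seed) || is.null(seed)) stop_plastex("seed is required")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      if (i %% 2L == 1L) {
        # tandem low-complexity: short unit over a repeat-like residue pool
        unit_len <- sample(3:8, 1L)
        unit <- paste(sample(c("S", "T", "K", "V", "E", "P", "I", "R", "G"),
                             unit_len, replace = TRUE), collapse = "")
        res <- substr(strrep(unit, ceiling(length / unit_len)), 1L, length)
        bio_seq(res, id = sprintf("decoy_lowcomp%02d", i),
                alphabet = "PROTEIN")
      } else {
        # myosin-like heptad: hydrophobic a/d positions, charged elsewhere
        heptad <- function() {
          p <- character(7)
          p[c(1, 4)] <- sample(c("L", "I", "V", "M"), 2L, replace = TRUE)
          p[c(2, 3, 5, 6, 7)] <- sample(c("E", "K", "Q", "R", "A", "S"),
                                        5L, replace = TRUE)
          paste(p, collapse = "")
        }
        res <- substr(paste(replicate(ceiling(length / 7), heptad()),
                            collapse = ""), 1L, length)
        bio_seq(res, id = sprintf("decoy_heptad%02d", i),
                alphabet = "PROTEIN")
      }
    })
  })
}
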