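test_that("FASTA reading normalises case and validates records", {
  path <- write_temp_fasta(list(a = REF$bases), "rec1")
  seqs <- read_sequences(path, "fasta")
  expect_length(seqs, 1)
  expect_equal(nchar(seqs[[1]]$bases), 16569)

  path2 <- write_temp_fasta(list(tolower("acgtacgt"), "GGGCCC"),
                            c("s1", "s2"))
  seqs2 <- read_sequences(path2, "fasta")
  expect_equal(seqs2[[1]]$bases, "ACGTACGT")
  expect_equal(seqs2[[2]]$bases, "GGGCCC")

  dup <- write_temp_fasta(list("ACGT", "AAAA"), c("x", "x"))
  expect_error(read_sequences(dup, "fasta"), "duplicate")

  bad <- write_temp_fasta(list("ACGTQCGT"), "bad1")
  expect_error(read_sequences(bad, "fasta"), "offset 5")
})

test_that("GenBank flat files parse accession and origin blocks", {
  gb <- c("LOCUS       KC911275             16569 bp    DNA     circular",
          "ACCESSION   KC911275",
          "FEATURES             Location/Qualifiers",
          "ORIGIN",
          "        1 acgtacgtac gtacgt",
          "//")
  path <- tempfile(fileext = ".gb")
  writeLines(gb, path)
  seqs <- read_sequences(path, "genbank")
  expect_equal(seqs[[1]]$sample_id, "KC911275")
  expect_equal(seqs[[1]]$bases, "ACGTACGTACGTACGT")
})

test_that("metadata joins onto sequences and flags missing samples", {
  path <- write_temp_fasta(list("ACGT"), "s1")
  seqs <- read_sequences(path, "fasta")
  md <- data.frame(sample_id = "s1", population = "P",
                   ethnic_group = "E", province = "V")
  out <- attach_metadata(seqs, md)
  expect_equal(out[[1]]$population, "P")
  expect_equal(out[[1]]$province, "V")
  expect_error(attach_metadata(seqs, data.frame(sample_id = "z",
                                                population = "P")),
               "missing from metadata")
})

test_that("identity alignment yields an empty profile over 16569 positions", {
  al <- align_to_reference(REF$bases, REF)
  expect_equal(al$identity, 1)
  p <- call_variants(al, REF)
  expect_equal(nrow(p$variants), 0)
  expect_equal(p$compared_length, 16569L)
})

test_that("point substitutions are scored with transition/transversion labels", {
  ch <- strsplit(REF$bases, "")[[1]]
  base73 <- ch[73]
  ch[73] <- transition_partner(base73)
  al <- align_to_reference(paste(ch, collapse = ""), REF)
  p <- call_variants(al, REF)
  expect_equal(p$variants$label, "73")
  expect_equal(p$variants$kind, "transition")

  # transversion keeps its base in the label
  ch2 <- strsplit(REF$bases, "")[[1]]
  tv <- setdiff(c("A", "C", "G", "T"),
                c(ch2[16318], transition_partner(ch2[16318])))[1]
  ch2[16318] <- tv
  p2 <- call_variants(align_to_reference(paste(ch2, collapse = ""), REF), REF)
  expect_equal(p2$variants$label, paste0("16318", tv))
  expect_equal(p2$variants$kind, "transversion")
})

test_that("banded alignment matches the reference aligner on small windows", {
  skip_if_not_installed("Biostrings")
  set.seed(42)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (rep in 1:15) {
    n <- sample(60:120, 1)
    refw <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    ch <- strsplit(refw, "")[[1]]
    ch[sample(n, 3)] <- sample(c("A", "C", "G", "T"), 3, TRUE)
    if (runif(1) < 0.5) { i <- sample(2:(n - 6), 1); ch <- ch[-(i:(i + 1))] }
    if (runif(1) < 0.5) ch <- append(ch, "C", after = sample(n - 3, 1))
    qry <- paste(ch, collapse = "")
    ours <- .align_banded(qry, refw, 1, -1, 8, 1, 60L)
    pa <- Biostrings::pairwiseAlignment(qry, refw, type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 8, gapExtension = 1)
    expect_equal(ours$score, Biostrings::score(pa))
  }
})

test_that("deletions are contiguous and left-aligned in homopolymer runs", {
  # delete one C from the 311..315 C run: left-aligned call is 311del
  ch <- strsplit(REF$bases, "")[[1]]
  ch <- ch[-314]
  p <- call_variants(align_to_reference(paste(ch, collapse = ""), REF,
                                        align_params(min_length = 16000L)),
                     REF)
  expect_equal(p$variants$label, "311del")

  # a 2-base deletion in unique sequence stays contiguous
  ch2 <- strsplit(REF$bases, "")[[1]]
  ch2 <- ch2[-c(5000, 5001)]
  p2 <- call_variants(align_to_reference(paste(ch2, collapse = ""), REF),
                      REF)
  dels <- p2$variants[p2$variants$kind == "deletion", ]
  expect_equal(nrow(dels), 2)
  expect_equal(diff(dels$position), 1)
  expect_equal(collapse_deletion_labels(p2$variants$label),
               paste0(dels$position[1], "-", dels$position[2], "del"))
})

test_that("insertions get pos.kN labels and IUPAC codes become missing data", {
  ch <- strsplit(REF$bases, "")[[1]]
  ins <- seq_with_variants(REF, ins = data.frame(position = 315, base = "A"))
  p <- call_variants(align_to_reference(ins, REF), REF)
  expect_equal(p$variants$label, "315.1A")
  expect_equal(p$variants$kind, "insertion")

  ch[400] <- "R"  # heteroplasmy-style ambiguity
  p2 <- call_variants(align_to_reference(paste(ch, collapse = ""), REF), REF)
  expect_equal(nrow(p2$variants), 0)
  expect_equal(p2$compared_length, 16568L)
  expect_equal(p2$missing_positions, 400L)
})

test_that("variant labels round-trip through the parser", {
  tvb <- setdiff(c("A", "C", "G", "T"),
                 c(ref_base(REF, 16318),
                   transition_partner(ref_base(REF, 16318))))[1]
  labs <- c("73", paste0("16318", tvb), "249del", "315.1C")
  v <- parse_variant_labels(labs, REF)
  expect_equal(variant_label(v$position, v$insert_index, v$kind, v$derived),
               labs)
  # a transversion written with its base parses back as a transition when
  # the base is the transition partner
  tp <- transition_partner(ref_base(REF, 100))
  v2 <- parse_variant_labels(paste0("100", tp), REF)
  expect_equal(v2$kind, "transition")
  expect_equal(v2$label, "100")
})

test_that("profiles recover randomly applied variant sets exactly", {
  set.seed(7)
  for (rep in 1:10) {
    pos <- sort(sample(setdiff(1000:15000, 4999:5003), 8))
    bases <- vapply(pos, function(p) transition_partner(ref_base(REF, p)),
                    character(1))
    seqstr <- seq_with_variants(REF, subs = data.frame(position = pos,
                                                       base = bases))
    p <- call_variants(align_to_reference(seqstr, REF), REF)
    expect_equal(p$variants$label, as.character(pos))
  }
})

test_that("masking drops hot spots and poly-C length variants, idempotently", {
  p <- profile_from_labels("x", c("73", "16519"), REF)
  expect_equal(profile_labels(apply_mask(p)), "73")

  pins <- profile_from_labels("y", "309.1C", REF)
  expect_equal(nrow(apply_mask(pins)$variants), 0)

  # substitutions inside the poly-C tract survive
  psub <- profile_from_labels("z", "305", REF)
  expect_equal(profile_labels(apply_mask(psub)), "305")

  pempty <- profile_from_labels("e", character(0), REF)
  expect_equal(nrow(apply_mask(pempty)$variants), 0)

  p2 <- profile_from_labels("w", c("73", "16182C", "16183C", "16519",
                                   "310.1C", "16190del"), REF)
  once <- apply_mask(p2)
  twice <- apply_mask(once)
  expect_identical(once$variants, twice$variants)
  expect_equal(profile_labels(once), "73")
})

test_that("functional annotation matches an independent codon translation", {
  skip_if_not_installed("Biostrings")
  expect_equal(annotate_variants(parse_variant_labels("16311", REF),
                                 ANN, REF), "noncoding")
  expect_equal(annotate_variants(parse_variant_labels("1000", REF),
                                 ANN, REF), "rna")
  code <- Biostrings::getGeneticCode("2")
  genes <- ANN[ANN$type == "coding", ]
  set.seed(11)
  checked_syn <- checked_nonsyn <- 0
  for (rep in 1:200) {
    g <- genes[sample.int(nrow(genes), 1), ]
    pos <- sample(g$start:g$end, 1)
    to <- sample(setdiff(c("A", "C", "G", "T"), ref_base(REF, pos)), 1)
    v <- data.frame(position = pos, insert_index = 0L,
                    kind = "transversion", derived = to,
                    label = paste0(pos, to))
    got <- annotate_variants(v, ANN, REF)
    # independent translation of the whole gene with Biostrings
    gseq <- substr(REF$bases, g$start, g$end)
    mseq <- gseq
    substr(mseq, pos - g$start + 1, pos - g$start + 1) <- to
    if (g$strand == "-") {
      gseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gseq)))
      mseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(mseq)))
    }
    ncod <- nchar(gseq) %/% 3
    aa_ref <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(gseq, 1, 3 * ncod)),
      genetic.code = code, no.init.codon = TRUE))
    aa_alt <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(mseq, 1, 3 * ncod)),
      genetic.code = code, no.init.codon = TRUE))
    in_complete_codon <- (if (g$strand == "-") g$end - pos else
      pos - g$start) < 3 * ncod
    if (in_complete_codon) {
      expected <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
      expect_equal(got, expected,
                   info = sprintf("%s at %d", g$region, pos))
      if (expected == "synonymous") checked_syn <- checked_syn + 1
      else checked_nonsyn <- checked_nonsyn + 1
    }
  }
  expect_gt(checked_syn, 5)
  expect_gt(checked_nonsyn, 5)
  # indel in a coding gene is frame-disrupting
  vind <- parse_variant_labels("3310del", REF)
  expect_equal(annotate_variants(vind, ANN, REF), "nonsynonymous")
  # classes partition the profile
  p <- profile_from_labels("x", c("73", "1000", "16311"), REF)
  expect_length(annotate_variants(p, ANN, REF), nrow(p$variants))
})

test_that("profile TSV and JSON round-trip", {
  p1 <- profile_from_labels("s1", c("73", "315.1C", "8281del", "8282del"),
                            REF)
  p2 <- profile_from_labels("s2", character(0), REF)
  path <- tempfile(fileext = ".tsv")
  write_profiles_tsv(list(p1, p2), path, collapse_deletions = TRUE)
  back <- read_profiles_tsv(path, REF)
  expect_equal(sort(profile_labels(back[[1]])), sort(profile_labels(p1)))
  expect_equal(length(profile_labels(back[[2]])), 0)
  jpath <- tempfile(fileext = ".json")
  write_profile_json(p1, jpath)
  j <- jsonlite::fromJSON(jpath)
  expect_equal(j$sample_id, "s1")
  expect_equal(nrow(j$variants), 4)
})

test_that("alignment guards reject non-mitogenome input", {
  expect_error(align_to_reference("ACGT", REF), "sanity window")
  junk <- paste(sample(c("A", "C", "G", "T"), 16569, TRUE), collapse = "")
  expect_error(align_to_reference(junk, REF), "identity")
})
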