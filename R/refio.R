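#' Read mitogenome sequences from FASTA or GenBank flat files
#'
#' @param path file path.
#' @param format `"fasta"` or `"genbank"`.
#' @return list of `mt_sequence` objects (fields: `sample_id`, `bases`,
#'   `population`, `ethnic_group`, `province`), bases upper-cased and
#'   validated against the IUPAC nucleotide alphabet.
#' @export
read_sequences <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: ", path)
  recs <- if (format == "fasta") {
    # BStringSet keeps invalid letters so they can be reported, not dropped
    ss <- Biostrings::readBStringSet(path)
    Map(function(id, s) list(sample_id = sub("\\s.*$", "", id),
                             bases = toupper(s)),
        names(ss), as.character(ss))
  } else {
    read_genbank_flat(path)
  }
  ids <- vapply(recs, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop_input("duplicate sequence ids: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  iupac <- c(names(Biostrings::IUPAC_CODE_MAP))
  lapply(recs, function(r) {
    if (!nzchar(r$bases)) stop_input("empty sequence for ", r$sample_id)
    ch <- strsplit(r$bases, "")[[1]]
    bad <- which(!(ch %in% iupac))
    if (length(bad))
      stop_input("non-IUPAC character '", ch[bad[1]], "' in record ",
                 r$sample_id, " at offset ", bad[1])
    structure(list(sample_id = r$sample_id, bases = r$bases,
                   population = NA_character_,
                   ethnic_group = NA_character_,
                   province = NA_character_),
              class = "mt_sequence")
  })
}

# Minimal GenBank flat-file reader: ACCESSION (fallback LOCUS) as id,
# ORIGIN block as sequence; records separated by "//".
read_genbank_flat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//", lines)
  if (!length(ends)) stop_input("no GenBank record terminator '//' in ", path)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(function(s, e) {
    block <- lines[s:(e - 1L)]
    acc <- grep("^ACCESSION", block, value = TRUE)
    loc <- grep("^LOCUS", block, value = TRUE)
    id <- if (length(acc)) strsplit(trimws(sub("^ACCESSION", "", acc[1])),
                                    "\\s+")[[1]][1]
          else if (length(loc)) strsplit(trimws(sub("^LOCUS", "", loc[1])),
                                         "\\s+")[[1]][1]
          else stop_input("GenBank record without ACCESSION or LOCUS in ", path)
    ori <- grep("^ORIGIN", block)
    if (!length(ori)) stop_input("GenBank record ", id, " has no ORIGIN block")
    seqlines <- block[(ori[1] + 1L):length(block)]
    bases <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
    list(sample_id = id, bases = bases)
  }, starts, ends)
}

#' Join population metadata onto sequences
#' @param seqs list of `mt_sequence`.
#' @param metadata data.frame with columns `sample_id`, `population` and
#'   optionally `ethnic_group`, `province`.
#' @export
attach_metadata <- function(seqs, metadata) {
  stopifnot(all(c("sample_id", "population") %in% names(metadata)))
  lapply(seqs, function(s) {
    i <- match(s$sample_id, metadata$sample_id)
    if (is.na(i)) stop_input("sample missing from metadata: ", s$sample_id)
    s$population <- as.character(metadata$population[i])
    if ("ethnic_group" %in% names(metadata))
      s$ethnic_group <- as.character(metadata$ethnic_group[i])
    if ("province" %in% names(metadata))
      s$province <- as.character(metadata$province[i])
    s
  })
}

#' Alignment parameters
#'
#' Defaults follow the common mtDNA-reporting convention: global alignment,
#' match +1 / mismatch -1, affine gap cost `8 + k` for a k-base gap, gaps
#' left-aligned on the reference. `band` is the half-width of the DP band
#' (`NULL`: chosen from the length difference). `identity_floor` flags
#' non-mitogenome inputs; `min_length`/`max_length` are the length sanity
#' window.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param band DP band half-width or `NULL`.
#' @param identity_floor minimum aligned identity.
#' @param min_length,max_length accepted sequence lengths.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = 8,
                         gap_extend = 1, band = NULL,
                         identity_floor = 0.9,
                         min_length = 16069L, max_length = 17069L) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, band = band,
       identity_floor = identity_floor,
       min_length = as.integer(min_length),
       max_length = as.integer(max_length))
}

#' Globally align a sample sequence to the reference
#'
#' Sequences are assumed to be linear strings already in reference register
#' (position 1 first), as mitogenome database records are; circular rotation
#' is not detected (such inputs fail the identity floor). Near-identical
#' pairs of equal length take an ungapped fast path; otherwise a banded
#' affine-gap Needleman-Wunsch (compiled) is used and gap runs are
#' left-normalised so indel placement is deterministic.
#'
#' @param seq an `mt_sequence` (or a plain character string).
#' @param ref a `reference_genome`.
#' @param params see [align_params()].
#' @return object of class `mt_alignment`: `sample_id`, `aligned_sample`,
#'   `aligned_ref` (equal-length strings with `-` for gaps), `score`,
#'   `identity`.
#' @export
align_to_reference <- function(seq, ref, params = align_params()) {
  bases <- if (inherits(seq, "mt_sequence")) seq$bases else toupper(seq)
  sid <- if (inherits(seq, "mt_sequence")) seq$sample_id else "sample"
  n <- nchar(bases); m <- nchar(ref$bases)
  if (n < params$min_length || n > params$max_length)
    stop_input("sequence ", sid, " length ", n,
               " outside sanity window [", params$min_length, ", ",
               params$max_length, "]")
  if (n == m) {
    # equal-length near-identical pairs: the ungapped alignment is optimal
    # unless a compensating insertion/deletion pair sits within a few
    # hundred bp, which would depress direct identity far below this bar
    a <- strsplit(bases, "")[[1]]; b <- strsplit(ref$bases, "")[[1]]
    idt <- mean(a == b)
    if (idt >= max(params$identity_floor, 0.95))
      return(new_alignment(sid, a, b, params))
  }
  band <- params$band %||% (abs(m - n) + 48L)
  res <- .align_banded(bases, ref$bases, params$match, params$mismatch,
                       params$gap_open, params$gap_extend, as.integer(band))
  a <- strsplit(res$aligned_sample, "")[[1]]
  b <- strsplit(res$aligned_ref, "")[[1]]
  norm <- normalize_gaps(a, b)
  new_alignment(sid, norm$a, norm$b, params)
}

new_alignment <- function(sample_id, a, b, params) {
  aligned <- a != "-" & b != "-"
  idt <- if (any(aligned)) mean(a[aligned] == b[aligned]) else 0
  if (idt < params$identity_floor)
    stop_input("alignment identity ", sprintf("%.3f", idt), " for ",
               sample_id, " below floor ", params$identity_floor,
               ": not a mitogenome in reference register?")
  structure(list(sample_id = sample_id,
                 aligned_sample = paste(a, collapse = ""),
                 aligned_ref = paste(b, collapse = ""),
                 identity = idt),
            class = "mt_alignment")
}

# Shift every gap run as far left as score-equivalence allows; iterated to a
# fixed point so merged runs keep moving. Makes indel placement independent
# of DP tie-breaking.
normalize_gaps <- function(a, b) {
  repeat {
    moved <- FALSE
    for (row in 1:2) {
      g <- if (row == 1) a == "-" else b == "-"
      if (!any(g)) next
      runs <- rle(g)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in which(runs$values)) {
        s <- starts[k]; e <- ends[k]
        if (row == 1) {
          while (s > 1L && a[s - 1L] != "-" && b[s - 1L] != "-" &&
                 b[s - 1L] == b[e]) {
            a[e] <- a[s - 1L]; a[s - 1L] <- "-"
            s <- s - 1L; e <- e - 1L; moved <- TRUE
          }
        } else {
          while (s > 1L && b[s - 1L] != "-" && a[s - 1L] != "-" &&
                 a[s - 1L] == a[e]) {
            b[e] <- b[s - 1L]; b[s - 1L] <- "-"
            s <- s - 1L; e <- e - 1L; moved <- TRUE
          }
        }
      }
    }
    if (!moved) break
  }
  list(a = a, b = b)
}

#' Score an alignment into a variant profile
#'
#' Transitions are labelled by bare position, transversions by position plus
#' base, deletions per reference position (`"249del"`), insertions in
#' `"315.1C"` style. IUPAC ambiguity codes produce no variant and the
#' affected reference position is dropped from `compared_length` (missing
#' data).
#'
#' @param alignment an `mt_alignment`.
#' @param ref the `reference_genome` the alignment was made against.
#' @return a `variant_profile`.
#' @export
call_variants <- function(alignment, ref) {
  stopifnot(inherits(alignment, "mt_alignment"))
  a <- strsplit(alignment$aligned_sample, "")[[1]]
  b <- strsplit(alignment$aligned_ref, "")[[1]]
  if (paste(b[b != "-"], collapse = "") != ref$bases)
    stop_input("alignment reference row does not match the reference genome")
  acgt <- c("A", "C", "G", "T")
  refcol <- b != "-"
  refpos <- cumsum(refcol)
  a_ok <- a %in% acgt
  # substitutions
  sub <- which(refcol & a_ok & a != b)
  # deletions (reference base against a gap)
  del <- which(refcol & a == "-")
  # insertions (sample base against a reference gap); ambiguous inserted
  # bases are dropped entirely
  ins <- which(!refcol & a_ok)
  if (length(ins) && any(refpos[ins] == 0L))
    stop_input("insertion before reference position 1 is not representable")
  # ambiguity codes at reference positions: missing data
  amb <- which(refcol & !a_ok & a != "-")
  compared <- sum(refcol) - length(amb)
  ins_idx <- integer(length(ins))
  if (length(ins)) {
    # gap runs at the same anchored reference position form one insertion
    ins_idx <- stats::ave(seq_along(ins), refpos[ins], FUN = seq_along)
  }
  pos <- c(refpos[sub], refpos[del], refpos[ins])
  int_idx <- c(integer(length(sub)), integer(length(del)), ins_idx)
  kind <- c(ifelse(is_transition(b[sub], a[sub]), "transition",
                   "transversion"),
            rep("deletion", length(del)), rep("insertion", length(ins)))
  der <- c(a[sub], rep("", length(del)), a[ins])
  v <- data.frame(position = as.integer(pos), insert_index = as.integer(int_idx),
                  kind = kind, derived = der,
                  label = variant_label(pos, int_idx, kind, der),
                  stringsAsFactors = FALSE)
  missing <- refpos[amb]
  variant_profile(alignment$sample_id, v, compared_length = compared,
                  missing_positions = missing)
}

#' Classify variants by functional consequence
#'
#' Substitutions in protein-coding genes are classified by codon translation
#' against the reference under the vertebrate mitochondrial genetic code;
#' substitutions in rRNA/tRNA intervals are `"rna"`, in the control region
#' `"noncoding"`. Indels in coding genes are frame-disrupting and classed
#' `"nonsynonymous"` by convention; substitutions in a trailing incomplete
#' codon are classed `"nonsynonymous"` as well.
#'
#' @param variants a `variant_profile` or a variant data.frame.
#' @param annotation gene table from [mt_annotation()].
#' @param ref the `reference_genome`.
#' @return character vector, one of `"synonymous"`, `"nonsynonymous"`,
#'   `"rna"`, `"noncoding"` per variant.
#' @export
annotate_variants <- function(variants, annotation, ref) {
  v <- if (inherits(variants, "variant_profile")) variants$variants else variants
  if (!nrow(v)) return(character(0))
  code <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  vapply(seq_len(nrow(v)), function(i) {
    p <- v$position[i]
    row <- which(annotation$start <= p & annotation$end >= p)
    if (!length(row)) stop_input("position ", p, " not covered by annotation")
    row <- row[1]
    type <- annotation$type[row]
    if (type == "control") return("noncoding")
    if (type == "rna") return("rna")
    if (v$kind[i] %in% c("insertion", "deletion")) return("nonsynonymous")
    gs <- annotation$start[row]; ge <- annotation$end[row]
    minus <- identical(annotation$strand[row], "-")
    off <- if (minus) ge - p else p - gs
    ci <- off %/% 3L
    within <- off %% 3L
    cod_pos <- if (minus) (ge - 3L * ci):(ge - 3L * ci - 2L)
               else (gs + 3L * ci):(gs + 3L * ci + 2L)
    if (any(cod_pos < gs | cod_pos > ge)) return("nonsynonymous")
    cod_ref <- ref_base(ref, sort(cod_pos))
    if (minus) cod_ref <- revcomp_chars(cod_ref)
    cod_alt <- cod_ref
    alt_base <- if (minus) revcomp_chars(v$derived[i]) else v$derived[i]
    cod_alt[within + 1L] <- alt_base
    aa_ref <- unname(code[paste(cod_ref, collapse = "")])
    aa_alt <- unname(code[paste(cod_alt, collapse = "")])
    if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous"
  }, character(1))
}
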