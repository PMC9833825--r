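# Coordinate convention used throughout: positions are counted from the first
# base of the start codon. Offset -n is n bases 5' of it (-1 adjoins the A of
# ATG); +1 is the A itself. The promoter motif spans offsets [-39, -1], the
# downstream control motif [+1, +39] of the coding strand. With the motif
# written 5'->3', offset -n sits at 1-based motif index 40 - n.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

as_read_seqs <- function(reads) {
  if (is.character(reads)) return(reads)
  if (is.data.frame(reads) && "seq" %in% names(reads)) return(reads$seq)
  if (inherits(reads, "DNAStringSet")) return(as.character(reads))
  stop("reads must be a character vector, a tibble with a `seq` column, ",
       "or a DNAStringSet", call. = FALSE)
}

#' Build the 39-bp promoter motif set
#'
#' From a reference sequence covering at least offsets -39..+39 around the
#' start codon, extracts the ancestral promoter motif (offsets -39..-1), one
#' evolved motif per declared adaptive SNP, the all-SNPs combination motif
#' when more than one SNP is declared, and the downstream coding-strand
#' control motif (+1..+39).
#'
#' @param reference Reference sequence (single character string, A/C/G/T).
#' @param start_codon_at 1-based position of the first base of the start codon
#'   within `reference`.
#' @param snps A data frame with columns `offset` (negative, in -39..-1),
#'   `from`, `to` (single bases); default the two canonical adaptive promoter
#'   SNPs -30T>A and -37C>T.
#' @param contaminants Optional named character vector of sequences whose
#'   presence (either strand) disqualifies a read, e.g. the homologous region
#'   of a different random promoter that cross-contaminated the library.
#' @return A tibble of class `motif_set` with columns `motif`, `role`
#'   (`ancestral`, `evolved`, `control`, `contaminant`), `sequence`.
#' @examples
#' ms <- build_motif_set(synthetic_p0_reference(), start_codon_at = 61)
#' ms
#' @export
build_motif_set <- function(reference, start_codon_at,
                            snps = canonical_p0_snps(),
                            contaminants = character()) {
  stopifnot(is.character(reference), length(reference) == 1)
  reference <- toupper(reference)
  if (start_codon_at - 39 < 1 || start_codon_at + 38 > nchar(reference)) {
    stop("reference too short: must cover offsets -39..+39 around the start ",
         "codon", call. = FALSE)
  }
  anc <- substr(reference, start_codon_at - 39, start_codon_at - 1)
  control <- substr(reference, start_codon_at, start_codon_at + 38)
  apply_snps <- function(motif, spec) {
    for (i in seq_len(nrow(spec))) {
      off <- spec$offset[i]
      if (off < -39 || off > -1) {
        stop("SNP offset outside the upstream window [-39, -1]: ", off,
             call. = FALSE)
      }
      pos <- 40 + off
      if (substr(motif, pos, pos) != toupper(spec$from[i])) {
        stop(sprintf("reference base at offset %d is %s, not %s", off,
                     substr(motif, pos, pos), spec$from[i]), call. = FALSE)
      }
      substr(motif, pos, pos) <- toupper(spec$to[i])
    }
    motif
  }
  rows <- list(tibble::tibble(motif = "ancestral", role = "ancestral",
                              sequence = anc))
  if (nrow(snps) > 0) {
    for (i in seq_len(nrow(snps))) {
      nm <- sprintf("%d%s>%s", snps$offset[i], snps$from[i], snps$to[i])
      rows <- c(rows, list(tibble::tibble(
        motif = nm, role = "evolved",
        sequence = apply_snps(anc, snps[i, , drop = FALSE]))))
    }
    if (nrow(snps) > 1) {
      rows <- c(rows, list(tibble::tibble(
        motif = "double", role = "evolved", sequence = apply_snps(anc, snps))))
    }
  }
  rows <- c(rows, list(tibble::tibble(motif = "control", role = "control",
                                      sequence = control)))
  if (length(contaminants) > 0) {
    nms <- names(contaminants)
    if (is.null(nms)) nms <- paste0("contaminant", seq_along(contaminants))
    rows <- c(rows, list(tibble::tibble(motif = nms, role = "contaminant",
                                        sequence = toupper(unname(contaminants)))))
  }
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$sequence[out$role %in% c("ancestral", "evolved")])) {
    stop("promoter motifs are not mutually distinct", call. = FALSE)
  }
  class(out) <- c("motif_set", class(out))
  out
}

#' @rdname build_motif_set
#' @export
canonical_p0_snps <- function() {
  tibble::tibble(offset = c(-30L, -37L), from = c("T", "C"), to = c("A", "T"))
}

#' Synthetic reference around the start codon
#'
#' A fixed 120-nt synthetic stand-in for the promoter/start-codon junction
#' (the true junction between the random promoter and the ribosome binding
#' site is construct-specific and must be supplied by the user for real data).
#' The start codon begins at position 61; the bases at offsets -30 (T) and
#' -37 (C) accept the canonical adaptive SNPs.
#'
#' @return A character string of length 120.
#' @export
synthetic_p0_reference <- function() {
  paste0(
    # offsets -60..-1 (synthetic promoter region; T at -30, C at -37)
    "GCATTAGCGGAACCTGTTAGCGACCGATCATGTACCCGGATGATTACGCTGAAGCCTTGA",
    # offsets +1..+60 (synthetic coding region starting with ATG)
    "ATGGCTCGTATTCCGAAAGGCACTGAACGTCTGGATAAACTGGCAGAAGTTATCGCAGAA"
  )
}

#' Count reads per promoter motif
#'
#' Each read is first screened against the contaminant motifs (exact substring
#' on either strand) and excluded if any matches. Remaining reads are assigned
#' to the promoter motif (ancestral or evolved) that occurs as an exact
#' substring of the read, on either strand; the motifs differ at fixed
#' positions of the same window, so at most one can match. Reads matching no
#' promoter motif are unassigned (this is where sequencing errors land: no
#' mismatches are tolerated). Matches to the downstream control motif are
#' tallied independently (a well-formed amplicon read matches both a promoter
#' motif and the control motif).
#'
#' @param reads Character vector of read sequences, a tibble with a `seq`
#'   column (e.g. from [read_fastq_reads()]), or a `DNAStringSet`.
#' @param motifs A `motif_set` from [build_motif_set()].
#' @return A tibble of class `motif_counts` with columns `motif`, `role`,
#'   `count`: one row per promoter motif, one per contaminant (excluded
#'   reads), one `control` row, and one `unassigned` row. The promoter rows
#'   plus `unassigned` plus the contaminant rows sum to the total read count
#'   (attribute `total`).
#' @export
count_motifs <- function(reads, motifs) {
  stopifnot(inherits(motifs, "motif_set"))
  seqs <- toupper(as_read_seqs(reads))
  if (length(seqs) == 0) stop("no reads", call. = FALSE)
  rc <- revcomp(seqs)
  match_either <- function(motif) {
    grepl(motif, seqs, fixed = TRUE) | grepl(motif, rc, fixed = TRUE)
  }
  cont <- motifs[motifs$role == "contaminant", ]
  excluded <- rep(FALSE, length(seqs))
  cont_counts <- integer(nrow(cont))
  for (i in seq_len(nrow(cont))) {
    hit <- match_either(cont$sequence[i]) & !excluded
    cont_counts[i] <- sum(hit)
    excluded <- excluded | hit
  }
  p0 <- motifs[motifs$role %in% c("ancestral", "evolved"), ]
  hits <- vapply(p0$sequence, match_either, logical(length(seqs)))
  hits <- matrix(hits, ncol = nrow(p0))
  hits[excluded, ] <- FALSE
  if (any(rowSums(hits) > 1)) {
    stop("a read matched more than one promoter motif; motifs are not ",
         "mutually exclusive in this read set", call. = FALSE)
  }
  ctrl <- motifs[motifs$role == "control", ]
  ctrl_count <- if (nrow(ctrl) == 1) sum(match_either(ctrl$sequence) & !excluded) else 0L
  assigned <- colSums(hits)
  unassigned <- sum(!excluded) - sum(assigned)
  out <- dplyr::bind_rows(
    tibble::tibble(motif = p0$motif, role = p0$role, count = as.integer(assigned)),
    tibble::tibble(motif = "control", role = "control",
                   count = as.integer(ctrl_count)),
    if (nrow(cont) > 0) tibble::tibble(motif = cont$motif, role = "contaminant",
                                       count = cont_counts),
    tibble::tibble(motif = "unassigned", role = "unassigned",
                   count = as.integer(unassigned))
  )
  class(out) <- c("motif_counts", class(out))
  attr(out, "total") <- length(seqs)
  out
}

#' Allele-fraction divergence metric
#'
#' For each evolved promoter motif, the number of reads carrying it divided by
#' the number of reads carrying the ancestral motif. Unassigned and excluded
#' reads do not enter. Normalizing to ancestral reads (rather than to cells)
#' deliberately down-weights SNPs sitting inside amplified arrays: a single
#' diverged copy among k tandem copies contributes 1 evolved per k - 1
#' ancestral templates, mirroring its 1/k chance of being the copy that
#' survives array contraction.
#'
#' @param counts A `motif_counts` tibble from [count_motifs()].
#' @return A tibble with one row per evolved motif: `motif`, `count`,
#'   `fraction`.
#' @export
divergence_fractions <- function(counts) {
  stopifnot(inherits(counts, "motif_counts"))
  anc <- counts$count[counts$role == "ancestral"]
  if (length(anc) != 1 || anc == 0) {
    stop("zero ancestral reads: divergence fraction undefined", call. = FALSE)
  }
  counts |>
    dplyr::filter(.data$role == "evolved") |>
    dplyr::transmute(.data$motif, .data$count,
                     fraction = .data$count / anc)
}

# all single-substitution variants of a motif (3 * nchar sequences)
one_mismatch_variants <- function(motif) {
  bases <- c("A", "C", "G", "T")
  n <- nchar(motif)
  chars <- strsplit(motif, "")[[1]]
  out <- character(0)
  for (i in seq_len(n)) {
    for (b in setdiff(bases, chars[i])) {
      v <- chars; v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

#' Single-SNP background fraction against a control motif
#'
#' Counts reads whose best match to the 39-bp control motif (over all
#' alignments, both strands) is at Hamming distance exactly 1, and divides by
#' the reads matching exactly (distance 0). This is the sequencing-error /
#' background-mutation control: under galactose selection no adaptive
#' mutation is expected inside the coding region, so this fraction should be
#' flat across conditions.
#'
#' @param reads As in [count_motifs()].
#' @param control_motif The 39-bp control sequence (character scalar), e.g.
#'   the `control` row of a [build_motif_set()].
#' @return Fraction (numeric scalar) of distance-1 reads per distance-0 read.
#' @export
single_snp_control <- function(reads, control_motif) {
  stopifnot(is.character(control_motif), length(control_motif) == 1)
  seqs <- toupper(as_read_seqs(reads))
  rc <- revcomp(seqs)
  exact <- grepl(control_motif, seqs, fixed = TRUE) |
    grepl(control_motif, rc, fixed = TRUE)
  n0 <- sum(exact)
  if (n0 == 0) stop("zero exact-match reads for the control motif",
                    call. = FALSE)
  variants <- one_mismatch_variants(toupper(control_motif))
  near <- rep(FALSE, length(seqs))
  todo <- !exact  # distance 0 dominates: only non-exact reads can be distance 1
  for (v in variants) {
    if (!any(todo)) break
    hit <- grepl(v, seqs[todo], fixed = TRUE) | grepl(v, rc[todo], fixed = TRUE)
    near[todo][hit] <- TRUE
    todo[todo] <- !hit
  }
  sum(near) / n0
}
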