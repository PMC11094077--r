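#' Read assembled contigs from a FASTA file
#'
#' Parses a (optionally gzip-compressed) FASTA file into a contig table.
#' Sequences are uppercased; the contig id is the first whitespace-delimited
#' token of the header line.
#'
#' @param path Path to a FASTA file.
#' @param source_tech Optional technology label recorded for every contig,
#'   one of `"long_read"` or `"short_read"`, or `NA`.
#' @param sample_id Optional sample label recorded for every contig.
#' @return A `data.frame` with columns `contig_id`, `sequence`, `length`,
#'   `source_tech`, `sample_id`; one row per FASTA record (zero rows for an
#'   empty file).
#' @export
read_fasta <- function(path, source_tech = NA_character_, sample_id = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (!is.na(source_tech))
    source_tech <- match.arg(source_tech, c("long_read", "short_read"))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate contig id(s) in ", path, ": ", paste(dup, collapse = ", "))
  data.frame(
    contig_id = ids,
    sequence = toupper(as.character(set)),
    length = Biostrings::width(set),
    source_tech = rep(source_tech, length(set)),
    sample_id = rep(sample_id, length(set)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a contig table to FASTA
#'
#' @param contigs Contig table as returned by [read_fasta()] (needs columns
#'   `contig_id`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  stopifnot(all(c("contig_id", "sequence") %in% names(contigs)))
  set <- Biostrings::DNAStringSet(contigs$sequence)
  names(set) <- contigs$contig_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read pairwise alignments (PAF or BLAST outfmt 6)
#'
#' Both dialects are normalized to one internal convention: 0-based half-open
#' coordinates on query and target, percent identity as a fraction in
#' `[0, 1]`. BLAST-6 `sstart > send` (reverse strand) target intervals are
#' flipped so `start < end`. BLAST-6 does not carry sequence lengths, so
#' `query_len`/`target_len` are `NA` unless `contig_lengths` is supplied.
#'
#' @param path Tab-separated alignment file.
#' @param dialect `"paf"` (12+ columns) or `"blast6"` (standard 12-column
#'   `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore`).
#' @param contig_lengths Optional named vector of contig lengths used to fill
#'   `query_len`/`target_len` for BLAST-6 input.
#' @return A `data.frame` with columns `query_id`, `target_id`, `query_start`,
#'   `query_end`, `target_start`, `target_end`, `n_matches`, `aln_len`,
#'   `pct_identity`, `query_len`, `target_len`.
#' @export
read_alignments <- function(path, dialect = c("paf", "blast6"),
                            contig_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- 12L
  bad <- which(nf < need)
  if (length(bad) > 0L)
    stop(dialect, " line ", bad[1L], " has ", nf[bad[1L]],
         " columns; expected >= ", need)
  if (dialect == "paf") {
    aln <- data.frame(
      query_id = vapply(fields, `[`, "", 1L),
      target_id = vapply(fields, `[`, "", 6L),
      query_start = as.numeric(vapply(fields, `[`, "", 3L)),
      query_end = as.numeric(vapply(fields, `[`, "", 4L)),
      target_start = as.numeric(vapply(fields, `[`, "", 8L)),
      target_end = as.numeric(vapply(fields, `[`, "", 9L)),
      n_matches = as.numeric(vapply(fields, `[`, "", 10L)),
      aln_len = as.numeric(vapply(fields, `[`, "", 11L)),
      query_len = as.numeric(vapply(fields, `[`, "", 2L)),
      target_len = as.numeric(vapply(fields, `[`, "", 7L)),
      stringsAsFactors = FALSE
    )
    aln$pct_identity <- ifelse(aln$aln_len > 0, aln$n_matches / aln$aln_len, 0)
  } else {
    pident <- as.numeric(vapply(fields, `[`, "", 3L))
    alen <- as.numeric(vapply(fields, `[`, "", 4L))
    qstart <- as.numeric(vapply(fields, `[`, "", 7L))
    qend <- as.numeric(vapply(fields, `[`, "", 8L))
    sstart <- as.numeric(vapply(fields, `[`, "", 9L))
    send <- as.numeric(vapply(fields, `[`, "", 10L))
    # 1-based inclusive -> 0-based half-open; normalize reverse-strand targets
    ts <- pmin(sstart, send) - 1
    te <- pmax(sstart, send)
    aln <- data.frame(
      query_id = vapply(fields, `[`, "", 1L),
      target_id = vapply(fields, `[`, "", 2L),
      query_start = qstart - 1,
      query_end = qend,
      target_start = ts,
      target_end = te,
      n_matches = round(pident / 100 * alen),
      aln_len = alen,
      query_len = NA_real_,
      target_len = NA_real_,
      stringsAsFactors = FALSE
    )
    aln$pct_identity <- pident / 100
    if (!is.null(contig_lengths)) {
      aln$query_len <- unname(contig_lengths[aln$query_id])
      aln$target_len <- unname(contig_lengths[aln$target_id])
    }
  }
  bad <- which(!(aln$query_start >= 0 & aln$query_start < aln$query_end) |
                 !(aln$target_start >= 0 & aln$target_start < aln$target_end))
  if (length(bad) > 0L)
    stop("invalid alignment interval on line ", bad[1L], " of ", path)
  aln[c("query_id", "target_id", "query_start", "query_end", "target_start",
        "target_end", "n_matches", "aln_len", "pct_identity", "query_len",
        "target_len")]
}

empty_alignments <- function() {
  data.frame(query_id = character(0), target_id = character(0),
             query_start = numeric(0), query_end = numeric(0),
             target_start = numeric(0), target_end = numeric(0),
             n_matches = numeric(0), aln_len = numeric(0),
             pct_identity = numeric(0), query_len = numeric(0),
             target_len = numeric(0), stringsAsFactors = FALSE)
}

#' Read per-base depth in the bedtools genomecov -d dialect
#'
#' Three tab-separated columns: contig id, 1-based position, depth. Positions
#' must run 1..L contiguously and in order within each contig (contigs may be
#' interleaved in the file as long as each contig's own rows are in order).
#'
#' @param path Path to the depth TSV (no header).
#' @return A named list of integer depth vectors, one per contig; index 1 of
#'   each vector is the contig's first base.
#' @export
read_depth_tsv <- function(path) {
  if (!file.exists(path)) stop("depth file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("contig", "pos", "depth"),
                           colClasses = c("character", "integer", "integer"))
  if (nrow(tab) == 0L) return(structure(list(), names = character(0)))
  if (any(tab$depth < 0)) stop("negative depth in ", path)
  tracks <- lapply(split(tab, factor(tab$contig, levels = unique(tab$contig))),
                   function(g) {
    if (!identical(g$pos, seq_len(nrow(g))))
      stop("positions for contig '", g$contig[1L],
           "' are not contiguous 1..L in order")
    g$depth
  })
  tracks
}

#' Write per-base depth tracks in the 3-column genomecov -d dialect
#'
#' @param tracks Named list of depth vectors (as from [read_depth_tsv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(tracks, path) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  tab <- do.call(rbind, lapply(names(tracks), function(id) {
    data.frame(contig = id, pos = seq_along(tracks[[id]]),
               depth = as.integer(tracks[[id]]), stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read SNV sites from a VCF file
#'
#' Retains single-nucleotide variant lines (REF and every ALT a single base)
#' and maps the first sample's AD field to per-base read counts. Indel and
#' other non-SNV lines are skipped; the number skipped is recorded in the
#' `n_skipped` attribute. Positions are converted to 0-based.
#'
#' @param path VCF 4.x file. Sites must carry `AD` (allele depths) in FORMAT.
#' @return A `data.frame` with columns `contig_id`, `pos` (0-based),
#'   `ref_allele`, `qual`, and integer count columns `count_A`, `count_C`,
#'   `count_G`, `count_T`; attribute `n_skipped` counts non-SNV lines.
#' @export
read_vcf_snvs <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  out <- data.frame(contig_id = character(0), pos = integer(0),
                    ref_allele = character(0), qual = numeric(0),
                    count_A = integer(0), count_C = integer(0),
                    count_G = integer(0), count_T = integer(0),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- 0L
  if (n == 0L) return(out)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no sample column with AD depths: ", path)
  ad <- vcfR::extract.gt(v, element = "AD")[, 1L]
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt_list <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  is_snv <- nchar(ref) == 1L &
    vapply(alt_list, function(a) length(a) >= 1L && all(nchar(a) == 1L) &&
             all(a %in% c("A", "C", "G", "T")), logical(1)) &
    ref %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snv)
  keep <- which(is_snv)
  if (length(keep) == 0L) {
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  counts <- matrix(0L, nrow = length(keep), ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(keep)) {
    k <- keep[i]
    if (is.na(ad[k]))
      stop("missing AD at ", fix[k, "CHROM"], ":", fix[k, "POS"])
    depths <- as.integer(strsplit(ad[k], ",", fixed = TRUE)[[1L]])
    alleles <- c(ref[k], alt_list[[k]])
    if (length(depths) != length(alleles))
      stop("AD length does not match allele count at ",
           fix[k, "CHROM"], ":", fix[k, "POS"])
    for (j in seq_along(alleles))
      counts[i, alleles[j]] <- counts[i, alleles[j]] + depths[j]
  }
  out <- data.frame(
    contig_id = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]) - 1L,
    ref_allele = ref[keep],
    qual = as.numeric(fix[keep, "QUAL"]),
    count_A = counts[, "A"], count_C = counts[, "C"],
    count_G = counts[, "G"], count_T = counts[, "T"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write an SNV table as a minimal single-sample VCF 4.2
#'
#' Inverse of [read_vcf_snvs()] for simulator output: each row becomes one
#' VCF line with the non-reference alleles observed at the site as ALT and a
#' `GT:AD:DP` sample field.
#'
#' @param snvs SNV table with the columns produced by [read_vcf_snvs()].
#' @param path Output path.
#' @param sample Sample name written in the header.
#' @return `path`, invisibly.
#' @export
write_vcf_snvs <- function(snvs, path, sample = "sample1") {
  bases <- c("A", "C", "G", "T")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  body <- vapply(seq_len(nrow(snvs)), function(i) {
    cnt <- as.integer(snvs[i, paste0("count_", bases)])
    names(cnt) <- bases
    ref <- snvs$ref_allele[i]
    alts <- bases[bases != ref & cnt > 0L]
    if (length(alts) == 0L) alts <- setdiff(bases, ref)[1L]  # monomorphic site
    ad <- paste(c(cnt[ref], cnt[alts]), collapse = ",")
    paste(snvs$contig_id[i], snvs$pos[i] + 1L, ".", ref,
          paste(alts, collapse = ","), format(snvs$qual[i]), "PASS", ".",
          "GT:AD:DP", paste0("0/1:", ad, ":", sum(cnt)), sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write intervals as BED
#'
#' Emits BED3 (or BED6 when `name`/`score` columns are present). Coordinates
#' are taken as already 0-based half-open, the package's internal convention.
#'
#' @param intervals `data.frame` with columns `contig_id`, `start`, `end` and
#'   optionally `name` and `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("contig_id", "start", "end") %in% names(intervals)))
  if (all(c("name", "score") %in% names(intervals))) {
    tab <- data.frame(intervals$contig_id, intervals$start, intervals$end,
                      intervals$name, intervals$score, ".")
  } else {
    tab <- data.frame(intervals$contig_id, intervals$start, intervals$end)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
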