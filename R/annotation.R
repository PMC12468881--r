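#' Build an annotation object from an exon table
#'
#' The annotation object is the package's container for transcript models.
#' All coordinates are 0-based half-open (`[start, end)`); conversion from
#' 1-based inclusive GTF happens at the I/O boundary only, so that the
#' context, cis and conservation layers share a single convention.
#'
#' @param exons a data frame with columns `transcript_id`, `gene_id`,
#'   `biotype` (one of `"lncRNA"`, `"protein_coding"`, `"circRNA"` or other),
#'   `chrom`, `start`, `end`, `strand` (`"+"`, `"-"` or `"."`), one row per
#'   exon.
#' @param chrom_sizes optional data frame with columns `chrom` and `size`
#'   (bp). When missing, sizes default to the furthest annotated coordinate
#'   per chromosome.
#' @return an object of class `lnc_annotation`: a list with tibbles `exons`
#'   (sorted), `transcripts` (one row per transcript with span `start`/`end`,
#'   `n_exons`, `spliced_length` and strand-aware `tss`) and `chrom_sizes`.
#' @export
annotation <- function(exons, chrom_sizes = NULL) {
  exons <- tibble::as_tibble(exons)
  need <- c("transcript_id", "gene_id", "biotype", "chrom", "start", "end", "strand")
  if (!all(need %in% names(exons))) {
    stop("`exons` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  validate_intervals(exons)
  exons <- dplyr::arrange(exons, .data$chrom, .data$start, .data$end, .data$transcript_id)

  if (nrow(exons) == 0) {
    tx0 <- tibble::tibble(
      transcript_id = character(), gene_id = character(), biotype = character(),
      chrom = character(), strand = character(), start = integer(),
      end = integer(), n_exons = integer(), spliced_length = integer(),
      tss = integer()
    )
    if (is.null(chrom_sizes)) {
      chrom_sizes <- tibble::tibble(chrom = character(), size = integer())
    }
    return(structure(list(exons = exons, transcripts = tx0,
                          chrom_sizes = tibble::as_tibble(chrom_sizes)),
                     class = "lnc_annotation"))
  }

  tx <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      gene_id = .data$gene_id[1],
      biotype = .data$biotype[1],
      n_exons = dplyr::n(),
      spliced_length = sum(.data$end - .data$start),
      n_chrom = dplyr::n_distinct(.data$chrom),
      n_strand = dplyr::n_distinct(.data$strand),
      overlap_free = !any(.data$start[-1] < cummax(.data$end)[-dplyr::n()]),
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    )
  bad <- tx$transcript_id[tx$n_chrom > 1 | tx$n_strand > 1]
  if (length(bad)) {
    stop("exons of one transcript must share chrom and strand: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- tx$transcript_id[!tx$overlap_free]
  if (length(bad)) {
    stop("overlapping exons within transcript: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tx <- tx |>
    dplyr::mutate(tss = ifelse(.data$strand == "-", .data$end, .data$start)) |>
    dplyr::select("transcript_id", "gene_id", "biotype", "chrom", "strand",
                  "start", "end", "n_exons", "spliced_length", "tss") |>
    dplyr::arrange(.data$transcript_id)

  if (is.null(chrom_sizes)) {
    chrom_sizes <- exons |>
      dplyr::group_by(chrom = .data$chrom) |>
      dplyr::summarise(size = max(.data$end), .groups = "drop")
  } else {
    chrom_sizes <- tibble::as_tibble(chrom_sizes)
    if (!all(c("chrom", "size") %in% names(chrom_sizes))) {
      stop("`chrom_sizes` must have columns `chrom` and `size`", call. = FALSE)
    }
    missing <- setdiff(unique(exons$chrom), chrom_sizes$chrom)
    if (length(missing)) {
      stop("chromosomes without a size: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(exons = exons, transcripts = tx,
         chrom_sizes = dplyr::arrange(chrom_sizes, .data$chrom)),
    class = "lnc_annotation"
  )
}

validate_intervals <- function(df, arg = deparse(substitute(df))) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop("negative start coordinate in `", arg, "`", call. = FALSE)
  if (any(df$end <= df$start)) {
    stop("`end` must exceed `start` (0-based half-open) in `", arg, "`", call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.' in `", arg, "`", call. = FALSE)
  }
  invisible(df)
}

#' @export
print.lnc_annotation <- function(x, ...) {
  cat("<lnc_annotation> ", nrow(x$transcripts), " transcripts (",
      paste(utils::capture.output(print(table(x$transcripts$biotype))),
            collapse = " "),
      ") on ", nrow(x$chrom_sizes), " chromosomes\n", sep = "")
  invisible(x)
}

# GTF I/O ---------------------------------------------------------------------

gtf_attr <- function(attrs, key) {
  stringr::str_match(attrs, paste0(key, '\\s+"([^"]*)"'))[, 2]
}

#' Parse GTF text into an annotation object
#'
#' Reads Ensembl-dialect GTF. Only `exon` feature lines are used; other
#' feature types are ignored. GTF 1-based inclusive coordinates are converted
#' to the package's internal 0-based half-open convention. The transcript
#' biotype is taken from the first of the `transcript_biotype`,
#' `gene_biotype` or `biotype` attributes; transcripts without one get
#' biotype `"unknown"`.
#'
#' @param text a single string or character vector of GTF lines.
#' @param chrom_sizes optional chromosome size table, see [annotation()].
#' @return an `lnc_annotation` object.
#' @export
parse_gtf <- function(text, chrom_sizes = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(annotation(empty_exon_tbl(), chrom_sizes))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    stop("GTF line ", idx[which(nf != 9)[1]], ": expected 9 tab-separated fields",
         call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  is_exon <- m[, 3] == "exon"
  if (!any(is_exon)) return(annotation(empty_exon_tbl(), chrom_sizes))
  m <- m[is_exon, , drop = FALSE]
  lineno <- idx[is_exon]

  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad)) {
    stop("GTF line ", lineno[bad[1]], ": non-numeric coordinates", call. = FALSE)
  }
  bad <- which(end1 < start1)
  if (length(bad)) {
    stop("GTF line ", lineno[bad[1]], ": end < start", call. = FALSE)
  }
  tid <- gtf_attr(m[, 9], "transcript_id")
  gid <- gtf_attr(m[, 9], "gene_id")
  bad <- which(is.na(tid) | is.na(gid))
  if (length(bad)) {
    stop("GTF line ", lineno[bad[1]],
         ": malformed attributes (transcript_id/gene_id missing)", call. = FALSE)
  }
  bt <- dplyr::coalesce(gtf_attr(m[, 9], "transcript_biotype"),
                        gtf_attr(m[, 9], "gene_biotype"),
                        gtf_attr(m[, 9], "biotype"),
                        "unknown")
  exons <- tibble::tibble(
    transcript_id = tid, gene_id = gid, biotype = bt,
    chrom = m[, 1], start = start1 - 1L, end = end1, strand = m[, 7]
  )
  annotation(exons, chrom_sizes)
}

empty_exon_tbl <- function() {
  tibble::tibble(transcript_id = character(), gene_id = character(),
                 biotype = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character())
}

#' Read a GTF file
#' @param file path to a GTF file.
#' @inheritParams parse_gtf
#' @return an `lnc_annotation` object.
#' @export
read_gtf <- function(file, chrom_sizes = NULL) {
  parse_gtf(readr::read_lines(file), chrom_sizes)
}

#' Serialize an annotation object to GTF text
#'
#' Emits one `exon` line per exon with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes, converting back to GTF 1-based inclusive
#' coordinates. `parse_gtf(format_gtf(ann))` reproduces `ann`'s models.
#'
#' @param ann an `lnc_annotation` object.
#' @return a character vector of GTF lines.
#' @export
format_gtf <- function(ann) {
  stopifnot(inherits(ann, "lnc_annotation"))
  e <- ann$exons
  if (nrow(e) == 0) return(character())
  sprintf(
    '%s\tlncatlas\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    e$chrom, e$start + 1L, e$end, e$strand, e$gene_id, e$transcript_id, e$biotype
  )
}

#' Write an annotation object to a GTF file
#' @inheritParams format_gtf
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gtf <- function(ann, file) {
  readr::write_lines(format_gtf(ann), file)
  invisible(file)
}

# BED I/O ---------------------------------------------------------------------

#' Format genomic intervals as BED6 text
#'
#' BED is already 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`, `name`
#'   and optionally `score` (default 0) and `strand` (default `"."`).
#' @return character vector of BED6 lines.
#' @export
format_bed <- function(intervals) {
  intervals <- tibble::as_tibble(intervals)
  if (nrow(intervals) == 0) return(character())
  if (!"score" %in% names(intervals)) intervals$score <- 0
  if (!"strand" %in% names(intervals)) intervals$strand <- "."
  validate_intervals(intervals)
  sprintf("%s\t%d\t%d\t%s\t%g\t%s",
          intervals$chrom, as.integer(intervals$start), as.integer(intervals$end),
          intervals$name, intervals$score, intervals$strand)
}

#' Write intervals to a BED6 file
#' @inheritParams format_bed
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_bed <- function(intervals, file) {
  readr::write_lines(format_bed(intervals), file)
  invisible(file)
}

#' Parse BED text into an interval tibble
#'
#' @param text a single string or character vector of BED lines (3 to 6
#'   columns; missing name/score/strand default to `"."`, 0, `"."`).
#' @return tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
parse_bed <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[!grepl("^\\s*(#|track|browser|$)", lines)]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          name = character(), score = double(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("BED line ", which(nf < 3)[1], ": fewer than 3 fields", call. = FALSE)
  }
  get <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, character(1))
  }
  out <- tibble::tibble(
    chrom = get(1, "."),
    start = as.integer(get(2, "0")),
    end = as.integer(get(3, "0")),
    name = get(4, "."),
    score = as.double(ifelse(get(5, "0") == ".", "0", get(5, "0"))),
    strand = get(6, ".")
  )
  validate_intervals(out, "bed")
  out
}

#' Read a BED file
#' @param file path to a BED file.
#' @return tibble as in [parse_bed()].
#' @export
read_bed <- function(file) parse_bed(readr::read_lines(file))

# Overlap queries -------------------------------------------------------------

#' Transcripts whose span overlaps a query interval
#'
#' Overlap is chromosome-matched and strand-agnostic; any shared base
#' (>= 1 bp under the half-open convention) counts. Unknown chromosomes
#' return an empty result rather than an error.
#'
#' @param ann an `lnc_annotation` object.
#' @param chrom chromosome name.
#' @param start,end query interval, 0-based half-open.
#' @return character vector of transcript ids, sorted.
#' @export
query_overlaps <- function(ann, chrom, start, end) {
  stopifnot(inherits(ann, "lnc_annotation"), end > start, start >= 0)
  tx <- ann$transcripts[ann$transcripts$chrom == chrom, ]
  if (nrow(tx) == 0) return(character())
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start + 1L, end),
    IRanges::IRanges(tx$start + 1L, tx$end)
  )
  sort(tx$transcript_id[S4Vectors::subjectHits(hits)])
}

# edge-to-edge distance between half-open spans; 0 when touching/overlapping
span_distance <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start1, start2) - pmin(end1, end2))
}
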