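# Readers and writers for the external formats the pipeline touches:
# FASTA sequences, conservation tracks (bedGraph / WIG), labeled pair
# tables and feature matrices (TSV).  All sequences are normalized to the
# uppercase RNA alphabet on input (T -> U), and all coordinates are
# 0-based, half-open [start, end) on the UTR, 5' -> 3'.

#' Construct a mature miRNA record
#'
#' @param id miRNA identifier.
#' @param sequence 5'->3' sequence; normalized to uppercase RNA (`T`->`U`).
#' @return An object of class `mature_mirna` with fields `id` and `sequence`.
#' @export
mature_mirna <- function(id, sequence) {
  sequence <- normalize_rna(sequence, id)
  n <- nchar(sequence)
  if (n < 15L || n > 30L)
    stop("miRNA '", id, "' has length ", n, "; expected 15-30 nt")
  structure(list(id = id, sequence = sequence), class = "mature_mirna")
}

#' Construct a 3' UTR record
#'
#' @param gene_id gene identifier.
#' @param sequence 5'->3' UTR sequence (DNA accepted, converted to RNA).
#' @param conservation optional numeric vector of per-base conservation
#'   scores in `[0, 1]`, same length as the sequence.
#' @return An object of class `utr_record`.
#' @export
utr_record <- function(gene_id, sequence, conservation = NULL) {
  sequence <- normalize_rna(sequence, gene_id)
  if (!is.null(conservation)) {
    if (length(conservation) != nchar(sequence))
      stop("conservation length (", length(conservation),
           ") != UTR length (", nchar(sequence), ") for '", gene_id, "'")
    if (any(conservation < 0 | conservation > 1))
      stop("conservation scores outside [0, 1] for '", gene_id, "'")
  }
  structure(list(gene_id = gene_id, sequence = sequence,
                 conservation = conservation), class = "utr_record")
}

normalize_rna <- function(sequence, id = "?") {
  s <- chartr("tu", "TU", toupper(sequence))
  s <- gsub("T", "U", s, fixed = TRUE)
  if (!nzchar(s)) stop("empty sequence for record '", id, "'")
  bad <- gsub("[ACGU]", "", s)
  if (nzchar(bad))
    stop("record '", id, "' contains non-RNA characters after ",
         "normalization: ", paste(unique(strsplit(bad, "")[[1]]),
                                  collapse = ", "))
  s
}

#' Read a FASTA file of miRNAs or UTRs
#'
#' Sequences are uppercased and `T` is rewritten to `U`; record ids are the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path FASTA file.
#' @param as `"mirna"` for mature miRNA records (length 15-30 enforced) or
#'   `"utr"` for UTR records.
#' @return A named list of [mature_mirna()] or [utr_record()] objects,
#'   in file order.
#' @export
read_fasta <- function(path, as = c("mirna", "utr")) {
  as <- match.arg(as)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in '", path, "'")
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "))
  seqs <- unname(as.character(set))
  recs <- lapply(seq_along(ids), function(i) {
    if (as == "mirna") mature_mirna(ids[i], seqs[i])
    else utr_record(ids[i], seqs[i])
  })
  names(recs) <- ids
  recs
}

#' Write records to FASTA
#'
#' @param records list of [mature_mirna()] / [utr_record()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- vapply(records, function(r) r$sequence, character(1))
  ids <- vapply(records, function(r) r$id %||% r$gene_id, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project a conservation track onto a UTR
#'
#' Reads a bedGraph or WIG track of per-base scores and returns one score
#' per UTR base.  Positions missing from the track are scored 0 (absence of
#' evidence of conservation), so averages over any interval are defined.
#' For minus-strand UTRs the projected array is reversed so that index `i`
#' matches sequence position `i`.
#'
#' @param path bedGraph (`.bedgraph`/`.bg`) or WIG (`.wig`) file.
#' @param utr a [utr_record()].
#' @param utr_genomic_start 0-based genomic start of the UTR on the track's
#'   chromosome.
#' @param strand `"+"` or `"-"`.
#' @param chrom optional chromosome name; defaults to the only chromosome
#'   present in the track.
#' @return Numeric vector of length `nchar(utr$sequence)` in `[0, 1]`.
#' @export
read_conservation <- function(path, utr, utr_genomic_start, strand = "+",
                              chrom = NULL) {
  stopifnot(strand %in% c("+", "-"))
  fmt <- track_format(path)
  validate_track_lines(path, fmt)
  gr <- tryCatch(
    suppressWarnings(rtracklayer::import(path, format = fmt)),
    error = function(e) stop("failed to parse track '", path, "': ",
                             conditionMessage(e)))
  n <- nchar(utr$sequence)
  scores <- numeric(n)
  if (length(gr) > 0L) {
    if (is.null(chrom)) chrom <- as.character(GenomicRanges::seqnames(gr)[1])
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    # genomic (1-based) -> UTR offsets (0-based)
    st <- GenomicRanges::start(gr) - 1L - utr_genomic_start
    en <- GenomicRanges::end(gr) - utr_genomic_start   # half-open end
    val <- GenomicRanges::mcols(gr)$score
    for (k in seq_along(st)) {
      lo <- max(st[k], 0L); hi <- min(en[k], n)
      if (hi > lo) scores[(lo + 1L):hi] <- val[k]
    }
  }
  if (strand == "-") scores <- rev(scores)
  scores
}

track_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bedgraph", "bg")) return("bedGraph")
  if (ext %in% c("wig", "wiggle")) return("wig")
  # sniff: wiggle tracks declare a step mode
  first <- readLines(path, n = 5L)
  if (any(grepl("^(fixedStep|variableStep)", first))) "wig" else "bedGraph"
}

validate_track_lines <- function(path, fmt) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^(track|browser|#)", ln)) next
    if (fmt == "wig" && grepl("^(fixedStep|variableStep)", ln)) next
    f <- strsplit(ln, "\\s+")[[1]]
    ok <- if (fmt == "bedGraph") {
      length(f) == 4L && !is.na(suppressWarnings(as.numeric(f[2]))) &&
        !is.na(suppressWarnings(as.numeric(f[3]))) &&
        !is.na(suppressWarnings(as.numeric(f[4])))
    } else {
      all(!is.na(suppressWarnings(as.numeric(f))))
    }
    if (!ok) stop("malformed ", fmt, " line ", i, " in '", path, "': ", ln)
  }
  invisible(TRUE)
}

#' Read / write a labeled miRNA-gene pair table
#'
#' Tab-separated with header; columns `mirna_id`, `gene_id`, `label`
#' (`positive`/`negative`) and optional `site_start`, `site_end` (0-based,
#' half-open on the UTR).
#'
#' @param path TSV file.
#' @param utrs optional named list of [utr_record()]s used to validate site
#'   coordinates against UTR lengths.
#' @return A data.frame.
#' @export
read_pair_table <- function(path, utrs = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("mirna_id", "gene_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pair table '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$label), c("positive", "negative"))
  if (length(bad))
    stop("unknown label token(s): ", paste(bad, collapse = ", "))
  if (all(c("site_start", "site_end") %in% names(df))) {
    has <- !is.na(df$site_start) & !is.na(df$site_end)
    if (any(has & df$site_end <= df$site_start))
      stop("pair table has site_end <= site_start")
    if (!is.null(utrs)) {
      len <- vapply(df$gene_id, function(g) {
        if (is.null(utrs[[g]])) NA_integer_ else nchar(utrs[[g]]$sequence)
      }, integer(1))
      over <- has & !is.na(len) & (df$site_end > len | df$site_start < 0)
      if (any(over))
        stop("site coordinates beyond UTR length for pair(s): ",
             paste(df$mirna_id[over], df$gene_id[over], sep = "/",
                   collapse = ", "))
    }
  }
  df
}

#' @rdname read_pair_table
#' @param pairs data.frame of pairs to write.
#' @export
write_pair_table <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a feature matrix
#'
#' TSV with a header naming identifier columns plus feature columns.  On
#' read, feature columns are reordered into the supplied canonical order;
#' a missing feature column is an error.
#'
#' @param path TSV file.
#' @param canonical character vector of feature names in canonical order
#'   (e.g. [site_feature_names()]); `NULL` keeps file order.
#' @return A data.frame with identifier columns first.
#' @export
read_feature_matrix <- function(path, canonical = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(canonical)) {
    miss <- setdiff(canonical, names(df))
    if (length(miss))
      stop("feature matrix '", path, "' missing feature column(s): ",
           paste(head(miss, 5L), collapse = ", "),
           if (length(miss) > 5L) ", ...")
    idcols <- setdiff(names(df), canonical)
    df <- df[, c(idcols, canonical), drop = FALSE]
  }
  df
}

#' @rdname read_feature_matrix
#' @param mat data.frame to write.
#' @export
write_feature_matrix <- function(mat, path) {
  write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
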