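# Coordinate conventions used throughout the package:
#  * tag and peak coordinates are 0-based half-open (BED convention);
#  * score-track probe positions are point coordinates on the axis the input
#    file uses (wiggle positions as printed; bedGraph probe center = floor
#    interval midpoint). Conversion happens only at parse/serialize time.

#' Construct a probe-level score track
#'
#' A score track holds, per chromosome, strictly increasing probe-center
#' positions and the standardized window scores attached to them (e.g. the
#' windowed t-statistics that tiling-array pipelines emit for one-color and
#' two-color platforms, or a ChIP-minus-input score difference). Duplicate
#' positions are collapsed by their mean so construction is order-independent.
#'
#' @param chroms named list; each element a list with numeric vectors
#'   `positions` and `scores` of equal length.
#' @param dataset_id,platform labels identifying the source experiment.
#' @param resolution nominal tiling resolution in bp (> 0).
#' @param max_interp_dist largest probe gap in bp across which linear
#'   interpolation is allowed; must be >= `resolution`.
#' @return An object of class `score_track`.
#' @seealso [read_score_track()], [interpolate_to_grid()]
#' @export
score_track <- function(chroms, dataset_id = "track", platform = "generic",
                        resolution = 35, max_interp_dist = resolution) {
  stopifnot(is.list(chroms), length(names(chroms)) == length(chroms))
  if (resolution <= 0) stop("resolution must be > 0")
  if (max_interp_dist < resolution)
    stop("max_interp_dist must be >= resolution")
  chroms <- lapply(chroms, function(ch) {
    pos <- as.numeric(ch$positions)
    sc <- as.numeric(ch$scores)
    if (length(pos) != length(sc)) stop("positions and scores differ in length")
    if (anyNA(pos) || any(!is.finite(sc)))
      stop("positions must be non-missing and scores finite")
    o <- order(pos)
    pos <- pos[o]; sc <- sc[o]
    if (anyDuplicated(pos)) {
      sc <- as.numeric(tapply(sc, pos, mean))
      pos <- sort(unique(pos))
    }
    list(positions = pos, scores = sc)
  })
  structure(list(dataset_id = dataset_id, platform = platform,
                 chroms = chroms, resolution = resolution,
                 max_interp_dist = max_interp_dist),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  n <- sum(vapply(x$chroms, function(ch) length(ch$positions), 0))
  cat(sprintf("score_track '%s' (%s): %d probes on %d chromosome(s), resolution %g bp, max interpolation gap %g bp\n",
              x$dataset_id, x$platform, n, length(x$chroms),
              x$resolution, x$max_interp_dist))
  invisible(x)
}

#' Read a score track from wiggle or bedGraph
#'
#' Fixed-step and variable-step wiggle positions are taken as the probe
#' centers; for bedGraph intervals the probe center is the floor of the
#' interval midpoint. Records at the same position are averaged.
#'
#' @param path file in wiggle (fixedStep/variableStep) or bedGraph format;
#'   the format is chosen by `format` or guessed from the file extension.
#' @param format one of `"auto"`, `"wig"`, `"bedGraph"`.
#' @inheritParams score_track
#' @return A [score_track()].
#' @export
read_score_track <- function(path, platform = "generic", resolution = 35,
                             max_interp_dist = resolution,
                             dataset_id = basename(path), format = "auto") {
  format <- match.arg(format, c("auto", "wig", "bedGraph"))
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bdg|bg)$", tolower(path))) "bedGraph" else "wig"
  }
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e) stop("failed to parse '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(gr) == 0) stop("empty score track: ", path)
  if (format == "bedGraph") {
    # floor midpoint of the 0-based half-open interval
    pos <- floor((BiocGenerics::start(gr) - 1 + BiocGenerics::end(gr)) / 2)
  } else {
    pos <- BiocGenerics::start(gr)
  }
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   pos = pos, score = gr$score)
  chroms <- lapply(split(df, df$chrom), function(d)
    list(positions = d$pos, scores = d$score))
  score_track(chroms, dataset_id = dataset_id, platform = platform,
              resolution = resolution, max_interp_dist = max_interp_dist)
}

#' Write a score track as variableStep wiggle
#'
#' @param track a [score_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=%s", track$dataset_id), con)
  for (chrom in names(track$chroms)) {
    ch <- track$chroms[[chrom]]
    writeLines(sprintf("variableStep chrom=%s", chrom), con)
    writeLines(sprintf("%d %.6g", as.integer(ch$positions), ch$scores), con)
  }
  invisible(path)
}

#' Construct a tag set
#'
#' A tag set stores one sequencing library as strand-aware 5'-end coordinates
#' only; read lengths are deliberately discarded, so libraries with different
#' read lengths can be combined as long as they are mapped to the same
#' reference. Records are kept sorted by (chrom, pos5, strand).
#'
#' @param tags data.frame with columns `chrom` (character), `pos5`
#'   (0-based integer 5'-end position, >= 0) and `strand` (`"+"` or `"-"`).
#' @param dataset_id label for the library.
#' @return An object of class `tag_set`.
#' @export
tag_set <- function(tags, dataset_id = "tags") {
  stopifnot(is.data.frame(tags),
            all(c("chrom", "pos5", "strand") %in% names(tags)))
  tags <- data.frame(chrom = as.character(tags$chrom),
                     pos5 = as.integer(tags$pos5),
                     strand = as.character(tags$strand),
                     stringsAsFactors = FALSE)
  if (nrow(tags)) {
    if (any(tags$pos5 < 0)) stop("negative 5' coordinates")
    if (!all(tags$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    tags <- tags[order(tags$chrom, tags$pos5, tags$strand), , drop = FALSE]
    rownames(tags) <- NULL
  }
  structure(list(dataset_id = dataset_id, tags = tags, n_tags = nrow(tags)),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("tag_set '%s': %d tags on %d chromosome(s) (%.1f%% Watson)\n",
              x$dataset_id, x$n_tags, length(unique(x$tags$chrom)),
              if (x$n_tags) 100 * mean(x$tags$strand == "+") else NA_real_))
  invisible(x)
}

#' Read mapped sequencing tags from a BED6 file
#'
#' The 5' end is the interval start for Watson-strand tags and `end - 1`
#' for Crick-strand tags (0-based).
#'
#' @param path BED file with at least 6 columns; every record needs a strand.
#' @param dataset_id label for the library.
#' @return A [tag_set()].
#' @export
read_tag_bed <- function(path, dataset_id = basename(path)) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("failed to parse '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  strand <- as.character(BiocGenerics::strand(gr))
  if (length(gr) && any(strand == "*"))
    stop("BED file lacks strand information (column 6): ", path)
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  pos5 <- ifelse(strand == "+", start0, end0 - 1L)
  tag_set(data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     pos5 = pos5, strand = strand),
          dataset_id = dataset_id)
}

#' Write a tag set to BED6
#'
#' Tags are serialized as fixed-length reads anchored at their 5' ends, the
#' inverse of [read_tag_bed()] for any read length.
#'
#' @param tags a [tag_set()].
#' @param path output file.
#' @param read_length nominal read length in bp (>= 1).
#' @return `path`, invisibly.
#' @export
write_tag_bed <- function(tags, path, read_length = 36L) {
  stopifnot(read_length >= 1)
  t <- tags$tags
  start <- ifelse(t$strand == "+", t$pos5, pmax(0L, t$pos5 - read_length + 1L))
  end <- ifelse(t$strand == "+", t$pos5 + read_length, t$pos5 + 1L)
  df <- data.frame(t$chrom, start, end,
                   name = paste0("t", seq_len(nrow(t))), score = 0L,
                   strand = t$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

peak_columns <- c("chrom", "start", "end", "name", "score", "summit",
                  "pvalue", "efdr", "n_datasets")

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), summit = integer(),
             pvalue = numeric(), efdr = numeric(), n_datasets = integer(),
             stringsAsFactors = FALSE)
}

validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks), all(peak_columns %in% names(peaks)))
  if (nrow(peaks)) {
    stopifnot(all(peaks$start < peaks$end),
              all(peaks$start <= peaks$summit), all(peaks$summit < peaks$end))
  }
  peaks[peak_columns]
}

#' Write called peaks to disk
#'
#' The `tabular` dialect is a tab-separated table with header
#' `#chrom start end name score summit pvalue efdr n_datasets`; the `bed`
#' dialect is BED6+2 with the summit carried in the thickStart/thickEnd
#' columns. Coordinates are 0-based half-open in both dialects.
#'
#' @param peaks a peak data.frame as returned by the peak callers.
#' @param path output file.
#' @param dialect `"tabular"` or `"bed"`.
#' @return `path`, invisibly.
#' @seealso [read_peaks()]
#' @export
write_peaks <- function(peaks, path, dialect = c("tabular", "bed")) {
  dialect <- match.arg(dialect)
  peaks <- validate_peaks(peaks)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "tabular") {
    writeLines(paste0("#", paste(peak_columns, collapse = "\t")), con)
    if (nrow(peaks))
      utils::write.table(format(peaks, digits = 15, trim = TRUE,
                                scientific = 10), con, sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    if (nrow(peaks)) {
      bed <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                        peaks$score, strand = ".",
                        thickStart = peaks$summit,
                        thickEnd = peaks$summit + 1L)
      utils::write.table(format(bed, digits = 15, trim = TRUE,
                                scientific = 10), con, sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read peaks written by [write_peaks()]
#'
#' @param path peak file.
#' @param dialect `"tabular"` or `"bed"`. The BED dialect does not carry
#'   p-values, eFDR or dataset counts; those fields come back as `NA`.
#' @return A peak data.frame.
#' @export
read_peaks <- function(path, dialect = c("tabular", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "tabular") {
    first <- readLines(path, n = 1)
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = peak_columns,
                            colClasses = c("character", "integer", "integer",
                                           "character", "numeric", "integer",
                                           "numeric", "numeric", "integer"),
                            skip = if (startsWith(first, "#")) 1L else 0L)
    if (!nrow(df)) return(empty_peaks())
    df
  } else {
    df <- tryCatch(utils::read.table(path, sep = "\t", header = FALSE),
                   error = function(e) NULL)
    if (is.null(df) || !nrow(df)) return(empty_peaks())
    data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
               end = as.integer(df[[3]]), name = as.character(df[[4]]),
               score = as.numeric(df[[5]]), summit = as.integer(df[[7]]),
               pvalue = NA_real_, efdr = NA_real_, n_datasets = NA_integer_,
               stringsAsFactors = FALSE)
  }
}

#' Read genomic regions from a BED file (first three columns)
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed_regions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#")
  data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), stringsAsFactors = FALSE)
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased; `N` is allowed. Duplicate identifiers or empty
#' sequences are errors.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate FASTA identifiers in ", path)
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0)) stop("empty sequence in ", path)
  names(seqs) <- nm
  seqs
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
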