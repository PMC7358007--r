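#' Convert 1-based inclusive coordinates to BED (0-based half-open)
#'
#' Printed genomic coordinates are 1-based inclusive; BED-family files are
#' 0-based half-open. The conversion is `start - 1, end` and its inverse
#' `start + 1, end`.
#'
#' @param start,end Coordinate vectors.
#' @return A tibble with converted start and end.
#' @examples
#' coords_to_bed(13021348, 46691226)  # 13021347, 46691226
#' @export
coords_to_bed <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  tibble(start = start - 1, end = end)
}

#' @rdname coords_to_bed
#' @export
bed_to_coords <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  tibble(start = start + 1, end = end)
}

stop_on_parse_problems <- function(x, path) {
  pr <- readr::problems(x)
  if (nrow(pr) > 0) {
    abort(sprintf("malformed lines in '%s': %s", path,
                  paste(sprintf("line %d (%s)", pr$row, pr$expected),
                        collapse = "; ")))
  }
  x
}

#' Read and write binned depth profiles as bedGraph
#'
#' bedGraph is 0-based half-open; in memory the profile is 1-based inclusive.
#'
#' @param depth Tibble with chrom, start, end, depth (1-based inclusive bins).
#' @param path File path.
#' @return `read_bedgraph()` returns the depth tibble; `write_bedgraph()`
#'   returns `path` invisibly.
#' @export
write_bedgraph <- function(depth, path) {
  out <- tibble(chrom = depth$chrom, start = depth$start - 1,
                end = depth$end, value = depth$depth)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                       col_types = "ciid", progress = FALSE)
  stop_on_parse_problems(x, path)
  tibble(chrom = x$chrom, start = as.integer(x$start + 1),
         end = as.integer(x$end), depth = x$value)
}

#' Read and write deletion calls or gene intervals as BED6
#'
#' @param intervals Tibble with chrom, start, end (1-based inclusive) and
#'   optionally a name column.
#' @param path File path.
#' @param name_col Column used for the BED name field.
#' @return `read_bed()` returns a tibble with 1-based inclusive coordinates.
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  nm <- if (!is.null(name_col) && name_col %in% names(intervals)) {
    intervals[[name_col]]
  } else {
    sprintf("region_%d", seq_len(nrow(intervals)))
  }
  out <- tibble(chrom = intervals$chrom, start = intervals$start - 1,
                end = intervals$end, name = nm, score = 0L, strand = ".")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path,
                       col_names = c("chrom", "start", "end", "name",
                                     "score", "strand"),
                       col_types = "ciicic", progress = FALSE)
  stop_on_parse_problems(x, path)
  tibble(chrom = x$chrom, start = as.integer(x$start + 1),
         end = as.integer(x$end), name = x$name)
}

#' Read and write the gene annotation as TSV
#'
#' Columns: gene_id, chrom, start, end (1-based inclusive), biotype, family,
#' ortholog_id, length.
#'
#' @param annotation Annotation tibble.
#' @param path File path.
#' @return `read_annotation()` returns the annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", chrom = "c", start = "i", end = "i", biotype = "c",
    family = "c", ortholog_id = "c", length = "i"), progress = FALSE)
  stop_on_parse_problems(x, path)
  if (any(x$start > x$end)) abort("annotation has intervals with start > end.")
  if (anyDuplicated(x$gene_id)) abort("annotation gene_id values must be unique.")
  x
}

#' Read and write long count tables as TSV
#'
#' Columns: gene_id, species, genotype, replicate, length, count,
#' library_size.
#'
#' @param counts Long count tibble.
#' @param path File path.
#' @return `read_counts()` returns the count tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("counts file '%s' not found.", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", species = "c", genotype = "c", replicate = "i",
    length = "i", count = "d", library_size = "d"), progress = FALSE)
  stop_on_parse_problems(x, path)
  x
}

#' Read per-cell detection tables or probe-trial tables as TSV
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_cells <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    tissue = "c", cell = "i", detected = "i"), progress = FALSE)
  stop_on_parse_problems(x, path)
  x
}

#' @rdname read_cells
#' @export
read_probe_trials <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    animal_id = "c", day = "i", trial = "i", zone_label = "c",
    time_fraction = "d"), progress = FALSE)
  stop_on_parse_problems(x, path)
  if (any(x$time_fraction < 0 | x$time_fraction > 1)) {
    abort("time fractions must lie in [0, 1].")
  }
  x
}

#' Read single-nucleotide variants from a VCF file
#'
#' Parses a VCF 4.x file via vcfR and returns the (chrom, pos, ref, alt)
#' keys. Body lines with a missing ALT allele or too few fields are rejected
#' with their line numbers before parsing.
#'
#' @param path VCF file path.
#' @return Tibble with chrom, pos, ref, alt.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF file '%s' not found.", path))
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  bad <- body[vapply(strsplit(lines[body], "\t"), function(f) {
    length(f) < 8 || f[5] %in% c("", ".")
  }, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("malformed VCF records (missing ALT or fields) at line(s): %s",
                  paste(bad, collapse = ", ")))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  tibble(chrom = fx$CHROM, pos = as.integer(fx$POS),
         ref = fx$REF, alt = fx$ALT)
}

#' Read a known-allele catalog as TSV
#'
#' @param path File path; columns chrom, pos, ref, alt.
#' @return A tibble.
#' @export
read_catalog <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c"), progress = FALSE)
  stop_on_parse_problems(x, path)
  x
}

#' Write a report object as JSON
#'
#' @param x A list of summaries.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
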