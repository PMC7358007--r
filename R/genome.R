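#' Transchromosome span length
#'
#' Length of the analysed arm between two printed 1-based coordinates,
#' reported in bp and in Mb rounded half-up to the nearest integer.
#'
#' @param start_bp,end_bp 1-based coordinates of the span boundaries
#'   (e.g. the recombination site and the telomere).
#' @return A one-row tibble with `span_bp` and `span_mb`.
#' @examples
#' transchromosome_span(13021348, 46691226)  # 33,669,878 bp ~ 34 Mb
#' @export
transchromosome_span <- function(start_bp, end_bp) {
  if (end_bp <= start_bp) abort("span must be positive (end_bp > start_bp).")
  bp <- end_bp - start_bp
  tibble(span_bp = bp, span_mb = floor(bp / 1e6 + 0.5))
}

#' Normalize a binned depth profile by its positive-bin median
#'
#' Divides every bin by the median depth of bins with positive depth, so that
#' the median normalized depth of covered bins is exactly 1. The
#' transchromosome is single copy, so true deletions sit near 0 on this scale.
#'
#' @param depth A tibble with at least a `depth` column (and typically chrom,
#'   start, end as produced by [sim_depth()] or [read_bedgraph()]).
#' @return The input tibble with an added `norm_depth` column.
#' @export
normalize_depth <- function(depth) {
  stopifnot("depth" %in% names(depth))
  pos <- depth$depth > 0
  if (!any(pos)) abort("cannot normalize an all-zero depth profile.")
  med <- median(depth$depth[pos])
  dplyr::mutate(depth, norm_depth = .data$depth / med)
}

#' Call deletions from a normalized depth profile
#'
#' Scans for maximal runs of bins with normalized depth below `threshold`,
#' merging runs separated by at most `merge_gap_bins` above-threshold bins,
#' and reports merged runs spanning at least `min_bins` bins. Calls are
#' bin-aligned, sorted by start, and non-overlapping.
#'
#' @param depth A normalized profile (see [normalize_depth()]); must contain
#'   chrom, start, end and norm_depth columns with bins in genomic order.
#' @param threshold Normalized-depth threshold below which a bin is "low";
#'   0.25 of the median tolerates mismapping background on a single-copy
#'   chromosome where true deletion depth is ~0.
#' @param min_bins Minimum bin span of a reported call.
#' @param merge_gap_bins Maximum run of above-threshold bins bridged inside
#'   one call.
#' @return A tibble of class `tc_deletions` with columns chrom, start, end,
#'   n_bins, mean_norm_depth.
#' @export
call_deletions <- function(depth, threshold = 0.25, min_bins = 3L,
                           merge_gap_bins = 1L) {
  if (!"norm_depth" %in% names(depth)) {
    abort("`depth` has no norm_depth column; run normalize_depth() first.")
  }
  stopifnot(threshold > 0, min_bins >= 1, merge_gap_bins >= 0)
  low <- which(depth$norm_depth < threshold)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_bins = integer(), mean_norm_depth = numeric())
  if (length(low) == 0) return(new_tc_deletions(empty))
  grp <- cumsum(c(1L, diff(low) > merge_gap_bins + 1L))
  calls <- purrr::map(split(low, grp), function(idx) {
    first <- min(idx); last <- max(idx)
    tibble(chrom = depth$chrom[first],
           start = depth$start[first],
           end = depth$end[last],
           n_bins = last - first + 1L,
           mean_norm_depth = mean(depth$norm_depth[first:last]))
  })
  calls <- dplyr::bind_rows(calls)
  calls <- calls[calls$n_bins >= min_bins, , drop = FALSE]
  calls <- calls[order(calls$start), , drop = FALSE]
  new_tc_deletions(if (nrow(calls)) calls else empty)
}

new_tc_deletions <- function(x) {
  class(x) <- c("tc_deletions", class(x))
  x
}

#' @exportS3Method generics::tidy
tidy.tc_deletions <- function(x, ...) {
  as_tibble(unclass_first(x))
}

#' @exportS3Method generics::glance
glance.tc_deletions <- function(x, span_bp = NA_real_, ...) {
  total <- if (nrow(x)) sum(x$end - x$start + 1) else 0
  tibble(n_calls = nrow(x), deleted_bp = total,
         frac_deleted = total / span_bp)
}

unclass_first <- function(x) {
  class(x) <- setdiff(class(x), class(x)[1])
  x
}

#' Annotate deletion calls with affected genes
#'
#' A gene is deleted iff its 1-based inclusive interval overlaps any call by
#' at least 1 bp (any-overlap convention). Returns per-gene flags, per-call
#' affected-gene counts, and totals including the fraction of the
#' transchromosome span that is deleted.
#'
#' @param calls A `tc_deletions` tibble (or any tibble with chrom/start/end).
#' @param annotation A gene annotation tibble (gene_id, chrom, start, end,
#'   biotype, ...).
#' @param span_bp Transchromosome span in bp used for the deleted fraction.
#' @return A list of class `tc_deletion_annotation` with elements `genes`,
#'   `calls` and `summary`; `tidy()` returns the per-gene table and
#'   `glance()` the one-row summary.
#' @export
annotate_deletions <- function(calls, annotation, span_bp) {
  if (nrow(calls) > 0 && !all(calls$chrom %in% unique(annotation$chrom))) {
    abort("calls and annotation are on different chromosomes / coordinate systems.")
  }
  stopifnot(span_bp > 0)
  hit <- overlaps_any(annotation$start, annotation$end,
                      as_tibble(calls)[, c("start", "end")])
  call_id <- rep(NA_integer_, nrow(annotation))
  if (nrow(calls) > 0 && any(hit)) {
    for (i in which(hit)) {
      call_id[i] <- which(annotation$start[i] <= calls$end &
                            annotation$end[i] >= calls$start)[1]
    }
  }
  genes <- dplyr::mutate(annotation, deleted = hit, call_id = call_id)
  per_call <- if (nrow(calls) > 0) {
    dplyr::mutate(
      as_tibble(calls), call_id = dplyr::row_number(),
      n_pcg = purrr::map_int(.data$call_id, function(k) {
        sum(genes$deleted & genes$call_id %in% k & genes$biotype == "PCG")
      }),
      n_npcg = purrr::map_int(.data$call_id, function(k) {
        sum(genes$deleted & genes$call_id %in% k & genes$biotype == "nonPCG")
      }))
  } else {
    tibble(chrom = character(), start = integer(), end = integer(),
           call_id = integer(), n_pcg = integer(), n_npcg = integer())
  }
  deleted_bp <- if (nrow(calls)) sum(calls$end - calls$start + 1) else 0
  summary <- tibble(
    n_calls = nrow(calls),
    n_deleted_pcg = sum(genes$deleted & genes$biotype == "PCG"),
    n_deleted_npcg = sum(genes$deleted & genes$biotype == "nonPCG"),
    deleted_bp = deleted_bp,
    frac_span_deleted = deleted_bp / span_bp
  )
  structure(list(genes = genes, calls = per_call, summary = summary),
            class = "tc_deletion_annotation")
}

#' @exportS3Method generics::tidy
tidy.tc_deletion_annotation <- function(x, ...) x$genes

#' @exportS3Method generics::glance
glance.tc_deletion_annotation <- function(x, ...) x$summary

#' Classify variants as known or novel against an allele catalog
#'
#' A variant is known iff its exact (chrom, pos, ref, alt) key appears in the
#' catalog of previously reported native alternative alleles.
#'
#' @param variants Tibble with columns chrom, pos, ref, alt.
#' @param catalog Tibble with the same key columns.
#' @return A tibble of class `tc_variants` with an added `known` column;
#'   `glance()` gives counts of known and novel variants.
#' @export
classify_variants <- function(variants, catalog) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  vk <- key(variants)
  if (anyDuplicated(vk)) {
    abort(paste0("duplicate variant keys: ",
                 paste(unique(vk[duplicated(vk)]), collapse = ", ")))
  }
  if (any(variants$ref == variants$alt)) {
    abort("variant ref and alt alleles must differ.")
  }
  out <- dplyr::mutate(variants, known = vk %in% key(catalog))
  class(out) <- c("tc_variants", class(out))
  out
}

#' @exportS3Method generics::glance
glance.tc_variants <- function(x, ...) {
  tibble(n = nrow(x), n_known = sum(x$known), n_novel = sum(!x$known))
}
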