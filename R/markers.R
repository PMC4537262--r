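#' Read a per-gene annotation table
#'
#' TSV with columns `gene`, `strain`, `contig`, `start`, `end`, and
#' optionally `strand`, `class` (functional category), `gh_family`,
#' `has_gaps` (alignment-gap/ambiguity flag). Coordinates are 1-based
#' inclusive (GFF convention).
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "strain", "contig", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table lacks column(s): ",
                         paste(miss, collapse = ", "))
  validate_annotations(df)
}

validate_annotations <- function(df) {
  if (any(df$start < 1 | df$end < 1)) stop("coordinates must be positive")
  if (any(df$start > df$end)) stop("start must be <= end")
  df
}

#' Select well-spaced housekeeping marker genes
#'
#' From candidate single-copy core genes mapped onto a reference genome,
#' keeps a set of genes pairwise separated by more than `min_spacing` bp
#' (gap measured between the closest gene ends, the conservative reading of
#' "distanced by more than 10 kb"). Conflicts are resolved by a greedy pass
#' over candidates sorted by length descending — within any cluster of
#' closely located genes the largest is kept — with ties broken by genomic
#' position, so the outcome is deterministic and invariant to input order.
#'
#' @param annotations annotation data.frame (see [read_annotations()]) for
#'   one reference strain; genes on different contigs never conflict.
#' @param candidates character vector of candidate gene ids (e.g. members of
#'   single-copy core groups without alignment gaps).
#' @param min_spacing required gap in bp (default 10000).
#' @return character vector of kept gene ids, ordered by genomic position.
#' @export
select_marker_loci <- function(annotations, candidates, min_spacing = 10000) {
  if (min_spacing <= 0) stop("min_spacing must be > 0")
  ann <- validate_annotations(as.data.frame(annotations))
  missing <- setdiff(candidates, ann$gene)
  if (length(missing))
    stop("candidate(s) without coordinates: ", paste(missing, collapse = ", "))
  ann <- ann[match(candidates, ann$gene), , drop = FALSE]
  ann$len <- ann$end - ann$start + 1
  ord <- order(-ann$len, ann$contig, ann$start, ann$gene)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (ann$contig[i] != ann$contig[j]) next
      gap <- max(ann$start[i], ann$start[j]) - min(ann$end[i], ann$end[j]) - 1
      if (gap <= min_spacing) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  kept <- kept[order(ann$contig[kept], ann$start[kept])]
  ann$gene[kept]
}
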