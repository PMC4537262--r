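#' Cut genome sequences into consecutive fragments
#'
#' Non-overlapping windows per contig (no chimeric fragments across contig
#' breaks). The trailing fragment is kept when at least `min_trailing` bp.
#' Fragment names encode contig and 0-based start (`contig:start`).
#'
#' @param sequences a [Biostrings::DNAStringSet] (or FASTA path).
#' @param size fragment size in bp (default 1020, the classical ANIb window).
#' @param min_trailing minimum length of the final partial fragment
#'   (default 100).
#' @return a [Biostrings::DNAStringSet] of fragments.
#' @export
fragment_genome <- function(sequences, size = 1020L, min_trailing = 100L) {
  sequences <- as_dnastringset(sequences)
  if (length(sequences) == 0L || sum(Biostrings::width(sequences)) == 0L)
    stop("empty input sequences")
  if (size < 1L) stop("size must be >= 1")
  frags <- list()
  for (i in seq_along(sequences)) {
    w <- Biostrings::width(sequences)[i]
    starts <- seq.int(1L, w, by = size)
    ends <- pmin(starts + size - 1L, w)
    len <- ends - starts + 1L
    keep <- len == size | len >= min_trailing
    starts <- starts[keep]
    ends <- ends[keep]
    if (!length(starts)) next
    fr <- Biostrings::extractAt(sequences[[i]],
                                IRanges::IRanges(starts, ends))
    names(fr) <- paste0(names(sequences)[i], ":", starts - 1L)
    frags[[i]] <- fr
  }
  if (!length(frags)) return(Biostrings::DNAStringSet())
  do.call(c, frags)
}

as_dnastringset <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (inherits(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  stop("cannot interpret input as DNA sequences")
}

# Internal seed-and-extend aligner: exact k-mer seeds locate the candidate
# diagonal, then a local pairwise alignment against a padded window scores
# it. Returns one row per fragment with a hit: nident, aln_length, qspan.
align_fragments_internal <- function(fragments, reference, seed_k = 16L,
                                     n_seeds = 8L, margin = 80L) {
  res <- vector("list", length(fragments))
  ref_seqs <- lapply(seq_along(reference), function(i) reference[[i]])
  for (fi in seq_along(fragments)) {
    frag <- fragments[[fi]]
    flen <- length(frag)
    k <- min(seed_k, flen)
    offs <- unique(as.integer(round(seq(1L, flen - k + 1L,
                                        length.out = min(n_seeds, flen - k + 1L)))))
    best <- NULL
    for (ci in seq_along(ref_seqs)) {
      subj <- ref_seqs[[ci]]
      diags <- integer(0)
      for (o in offs) {
        seed <- Biostrings::subseq(frag, o, o + k - 1L)
        hits <- Biostrings::start(Biostrings::matchPattern(seed, subj))
        if (length(hits)) diags <- c(diags, hits - o + 1L)
      }
      if (!length(diags)) next
      # cluster implied fragment starts within +/- margin; try the densest
      cl <- sort(table(round(diags / 25)), decreasing = TRUE)
      cand <- as.integer(names(cl))[seq_len(min(2L, length(cl)))] * 25L
      for (st in cand) {
        ws <- max(1L, st - margin)
        we <- min(length(subj), st + flen - 1L + margin)
        win <- Biostrings::subseq(subj, ws, we)
        aln <- Biostrings::pairwiseAlignment(
          frag, win, type = "local",
          substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -1, baseOnly = FALSE),
          gapOpening = 2, gapExtension = 1)
        ni <- Biostrings::nmatch(aln)
        if (is.null(best) || ni > best$nident) {
          pr <- Biostrings::pattern(aln)
          best <- list(
            nident = ni,
            aln_length = Biostrings::nchar(aln),
            qspan = Biostrings::end(pr) - Biostrings::start(pr) + 1L)
        }
      }
    }
    if (!is.null(best))
      res[[fi]] <- data.frame(fragment = names(fragments)[fi],
                              frag_length = flen,
                              nident = best$nident,
                              aln_length = best$aln_length,
                              qspan = best$qspan)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(fragment = character(0), frag_length = integer(0),
                      nident = integer(0), aln_length = integer(0),
                      qspan = integer(0))
  out
}

# blastn adapter reproducing the classical ANIb settings (reward 1,
# penalty -1, no dusting); requires makeblastdb/blastn on PATH.
align_fragments_blastn <- function(fragments, reference) {
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "")
    stop("blastn/makeblastdb not found on PATH")
  td <- tempfile("anib")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "frags.fasta")
  rf <- file.path(td, "ref.fasta")
  Biostrings::writeXStringSet(fragments, qf)
  Biostrings::writeXStringSet(reference, rf)
  db <- file.path(td, "refdb")
  system2("makeblastdb", c("-in", rf, "-dbtype", "nucl", "-out", db),
          stdout = FALSE, stderr = FALSE)
  out <- file.path(td, "hits.tsv")
  system2("blastn",
          c("-task", "blastn", "-query", qf, "-db", db,
            "-reward", "1", "-penalty", "-1", "-gapopen", "2",
            "-gapextend", "1", "-xdrop_gap", "150", "-dust", "no",
            "-evalue", "1e-5", "-max_target_seqs", "5",
            "-outfmt", shQuote("6 qseqid nident length qstart qend bitscore"),
            "-out", out),
          stdout = FALSE, stderr = FALSE)
  hits <- tryCatch(
    utils::read.delim(out, header = FALSE,
                      col.names = c("fragment", "nident", "aln_length",
                                    "qstart", "qend", "bitscore")),
    error = function(e) NULL)
  flen <- stats::setNames(Biostrings::width(fragments), names(fragments))
  if (is.null(hits) || nrow(hits) == 0)
    return(data.frame(fragment = character(0), frag_length = integer(0),
                      nident = integer(0), aln_length = integer(0),
                      qspan = integer(0)))
  hits <- hits[order(hits$fragment, -hits$bitscore), ]
  hits <- hits[!duplicated(hits$fragment), ]
  data.frame(fragment = hits$fragment,
             frag_length = as.integer(flen[hits$fragment]),
             nident = hits$nident, aln_length = hits$aln_length,
             qspan = abs(hits$qend - hits$qstart) + 1L)
}

#' One-directional fragment-based ANI (ANIb)
#'
#' The query genome is cut into fragments (default 1020 bp) and each fragment
#' is locally aligned to the reference. Per fragment, the *overall identity*
#' is identities / fragment length (identity recalculated along the entire
#' fragment) and the *alignable fraction* is the aligned fragment span /
#' fragment length. Matches with overall identity > `min_identity` and
#' alignable fraction >= `min_alignable` are retained, and ANI is the mean
#' *local* identity (identities / alignment length) of retained matches, in
#' percent.
#'
#' @param query,reference genome sequences ([Biostrings::DNAStringSet] or
#'   FASTA paths).
#' @param fragment_size fragment window (default 1020 bp).
#' @param min_identity overall-identity retention threshold (default 0.30).
#' @param min_alignable alignable-fraction retention threshold (default 0.70).
#' @param aligner `"internal"` (dependency-free seed-and-extend),
#'   `"blastn"` (external adapter), or a function
#'   `(fragments, reference) -> data.frame(fragment, frag_length, nident,
#'   aln_length, qspan)`.
#' @param query_id,reference_id labels for the result.
#' @return an `ani_result`: `query`, `reference`, `n_fragments`,
#'   `n_retained`, `ani` (percent; `NA` and `defined = FALSE` when no
#'   fragment passes the filters), `fragments` (per-fragment diagnostics).
#' @export
ani_pair <- function(query, reference, fragment_size = 1020L,
                     min_identity = 0.30, min_alignable = 0.70,
                     aligner = c("internal", "blastn"),
                     query_id = "query", reference_id = "reference") {
  query <- as_dnastringset(query)
  reference <- as_dnastringset(reference)
  if (sum(Biostrings::width(query)) == 0 ||
      sum(Biostrings::width(reference)) == 0)
    stop("both genomes must be non-empty")
  align <- if (is.function(aligner)) aligner
           else switch(match.arg(aligner),
                       internal = align_fragments_internal,
                       blastn = align_fragments_blastn)
  frags <- fragment_genome(query, size = fragment_size)
  hits <- align(frags, reference)
  hits$overall_identity <- hits$nident / hits$frag_length
  hits$alignable_fraction <- hits$qspan / hits$frag_length
  hits$local_identity <- hits$nident / hits$aln_length
  hits$retained <- hits$overall_identity > min_identity &
    hits$alignable_fraction >= min_alignable
  retained <- hits[hits$retained, , drop = FALSE]
  ani <- if (nrow(retained)) 100 * mean(retained$local_identity) else NA_real_
  structure(list(query = query_id, reference = reference_id,
                 n_fragments = length(frags),
                 n_retained = nrow(retained),
                 ani = ani, defined = nrow(retained) > 0,
                 fragments = hits),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ani_result: %s vs %s — ANI %s%% (%d/%d fragments retained)\n",
              x$query, x$reference,
              if (x$defined) sprintf("%.2f", x$ani) else "undefined",
              x$n_retained, x$n_fragments))
  invisible(x)
}

#' Pairwise ANI matrix with complete-linkage clustering
#'
#' Both directions are computed for each pair and the reported value is their
#' mean. The tree is complete-linkage clustering on distance `100 - ANI`;
#' pairs with undefined ANI are excluded from clustering with a warning.
#'
#' @param genomes named list of genome sequences (each a
#'   [Biostrings::DNAStringSet] or FASTA path).
#' @param ... passed to [ani_pair()].
#' @return list with `ani` (symmetric percent matrix, diagonal 100),
#'   `directional` (matrix of one-way ANIs), `tree`, `newick`.
#' @export
ani_matrix <- function(genomes, ...) {
  if (length(genomes) < 2) stop("need at least 2 genomes")
  if (is.null(names(genomes)))
    names(genomes) <- paste0("genome", seq_along(genomes))
  ids <- names(genomes)
  genomes <- lapply(genomes, as_dnastringset)
  n <- length(genomes)
  dir_ani <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(dir_ani) <- 100
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- ani_pair(genomes[[i]], genomes[[j]],
                  query_id = ids[i], reference_id = ids[j], ...)
    dir_ani[i, j] <- r$ani
  }
  ani <- (dir_ani + t(dir_ani)) / 2
  tree <- NULL
  newick <- NA_character_
  usable <- rowSums(is.na(ani)) == 0
  if (any(!usable))
    warning("excluding from clustering (undefined ANI): ",
            paste(ids[!usable], collapse = ", "))
  if (sum(usable) >= 2) {
    sub <- ani[usable, usable, drop = FALSE]
    hc <- stats::hclust(stats::as.dist(100 - sub), method = "complete")
    tree <- ape::as.phylo(hc)
    newick <- ape::write.tree(tree)
  }
  list(ani = ani, directional = dir_ani, tree = tree, newick = newick)
}
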