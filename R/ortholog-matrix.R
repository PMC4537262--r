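#' Ortholog occurrence matrix
#'
#' The central object of the pipeline: a strains x ortholog-groups matrix of
#' non-negative integer occurrence counts (presence = count >= 1), with
#' optional per-group metadata (functional class, representative gene length).
#'
#' @param occurrence integer matrix, strains in rows, ortholog groups in
#'   columns. Dimnames are taken as strain / group identifiers; unnamed
#'   dimensions get `S1..Sn` / zero-padded `G...` identifiers.
#' @param group_meta optional data.frame keyed by a `group` column, with
#'   further columns such as `class` (functional category) or `length`.
#'
#' @return an object of class `ortholog_matrix` with fields `strains`,
#'   `groups`, `occurrence`, `group_meta`.
#' @export
ortholog_matrix <- function(occurrence, group_meta = NULL) {
  occurrence <- as.matrix(occurrence)
  if (is.logical(occurrence)) occurrence[] <- as.integer(occurrence)
  if (!is.numeric(occurrence)) stop("'occurrence' must be numeric")
  if (any(occurrence < 0) || any(occurrence != round(occurrence)))
    stop("'occurrence' must hold non-negative integer counts")
  storage.mode(occurrence) <- "integer"
  if (is.null(rownames(occurrence)))
    rownames(occurrence) <- paste0("S", seq_len(nrow(occurrence)))
  if (is.null(colnames(occurrence)))
    colnames(occurrence) <- group_ids(ncol(occurrence))
  if (anyDuplicated(rownames(occurrence)))
    stop("duplicate strain ids")
  if (anyDuplicated(colnames(occurrence)))
    stop("duplicate group ids")
  if (!is.null(group_meta)) {
    group_meta <- as.data.frame(group_meta)
    if (is.null(group_meta$group)) stop("group_meta needs a 'group' column")
    group_meta <- group_meta[match(colnames(occurrence), group_meta$group), ,
                             drop = FALSE]
    rownames(group_meta) <- NULL
  }
  structure(
    list(strains = rownames(occurrence), groups = colnames(occurrence),
         occurrence = occurrence, group_meta = group_meta),
    class = "ortholog_matrix")
}

group_ids <- function(n, prefix = "G") {
  if (n == 0) return(character(0))
  sprintf("%s%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}

#' @export
print.ortholog_matrix <- function(x, ...) {
  occ <- x$occurrence
  cat(sprintf("ortholog_matrix: %d strains x %d groups\n",
              nrow(occ), ncol(occ)))
  if (ncol(occ)) {
    pres <- occ >= 1L
    cat(sprintf("  presence: %d cells (%.1f%%); paralogous groups: %d; singleton groups: %d\n",
                sum(pres), 100 * mean(pres),
                sum(apply(occ > 1L, 2, any)),
                sum(colSums(pres) == 1L)))
  }
  if (!is.null(x$group_meta))
    cat(sprintf("  group_meta columns: %s\n",
                paste(setdiff(names(x$group_meta), "group"), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ortholog_matrix <- function(x) dim(x$occurrence)

# binary presence view, 0/1 integer
presence <- function(m) {
  stopifnot(inherits(m, "ortholog_matrix"))
  p <- m$occurrence
  p[] <- as.integer(p >= 1L)
  p
}

#' Subset an ortholog matrix by strains and/or groups
#'
#' @param m an [ortholog_matrix()].
#' @param strains,groups character vectors of ids to keep (default all).
#' @param drop_empty drop groups left with no occurrence after strain
#'   subsetting (default `TRUE`, preserving the no-all-zero-column invariant).
#' @return an `ortholog_matrix`.
#' @export
subset_matrix <- function(m, strains = NULL, groups = NULL, drop_empty = TRUE) {
  stopifnot(inherits(m, "ortholog_matrix"))
  occ <- m$occurrence
  if (!is.null(strains)) {
    bad <- setdiff(strains, m$strains)
    if (length(bad)) stop("unknown strain id(s): ", paste(bad, collapse = ", "))
    occ <- occ[strains, , drop = FALSE]
  }
  if (!is.null(groups)) {
    bad <- setdiff(groups, m$groups)
    if (length(bad)) stop("unknown group id(s): ", paste(bad, collapse = ", "))
    occ <- occ[, groups, drop = FALSE]
  }
  if (drop_empty && ncol(occ)) occ <- occ[, colSums(occ) > 0L, drop = FALSE]
  meta <- m$group_meta
  if (!is.null(meta)) meta <- meta[match(colnames(occ), meta$group), , drop = FALSE]
  ortholog_matrix(occ, meta)
}

#' Read an OrthoMCL-style groups file
#'
#' Each line is `groupID: strainA|gene1 strainB|gene2 ...`. Occurrence counts
#' are the number of member genes per strain per group, so paralogs are
#' preserved. The strain id is everything before the first `|`; gene ids may
#' themselves contain `|`.
#'
#' @param path path to the groups file.
#' @param strain_roster optional character vector; strains in the roster but
#'   absent from the file appear as all-zero rows, and the row order follows
#'   the roster.
#' @return an [ortholog_matrix()].
#' @export
read_groups <- function(path, strain_roster = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  gids <- character(length(lines))
  members <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0)
      stop(sprintf("parse error at line %d: no ':' separator", i))
    gids[[i]] <- trimws(substr(ln, 1L, colon - 1L))
    toks <- strsplit(trimws(substr(ln, colon + 1L, nchar(ln))), "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    bad <- !grepl("|", toks, fixed = TRUE)
    if (any(bad))
      stop(sprintf("parse error at line %d: member token '%s' lacks '|'",
                   i, toks[bad][1]))
    members[[i]] <- sub("\\|.*$", "", toks)
  }
  if (anyDuplicated(gids)) stop("duplicate group ids in groups file")
  strains <- unique(unlist(members))
  if (is.null(strains)) strains <- character(0)
  if (!is.null(strain_roster)) strains <- union(strain_roster, strains)
  occ <- matrix(0L, length(strains), length(gids),
                dimnames = list(strains, gids))
  for (i in seq_along(members)) {
    tb <- table(members[[i]])
    occ[names(tb), i] <- as.integer(tb)
  }
  ortholog_matrix(occ)
}

#' Write an ortholog matrix as an OrthoMCL-style groups file
#'
#' Round-trip partner of [read_groups()]: a strain with occurrence count c in
#' a group contributes c member tokens `strain|<group>_<strain>_k`, so
#' presence/absence and paralog multiplicity both survive the round trip.
#'
#' @param m an [ortholog_matrix()] with at least one group.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_groups_file <- function(m, path) {
  stopifnot(inherits(m, "ortholog_matrix"))
  if (ncol(m$occurrence) == 0L) stop("matrix has no groups to write")
  occ <- m$occurrence
  lines <- vapply(seq_len(ncol(occ)), function(j) {
    cnt <- occ[, j]
    idx <- which(cnt > 0L)
    toks <- unlist(lapply(idx, function(i) {
      s <- rownames(occ)[i]
      k <- cnt[i]
      g <- if (k == 1L) paste0("g", j) else paste0("g", j, ".", seq_len(k))
      paste0(s, "|", g)
    }))
    paste0(colnames(occ)[j], ": ", paste(toks, collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a strain x group TSV occurrence matrix
#'
#' Header row holds group ids, first column strain ids; cells are counts
#' (0/1 for binary matrices).
#'
#' @param path TSV path.
#' @return [ortholog_matrix()] for `read_matrix_tsv`; `path` invisibly for
#'   `write_matrix_tsv`.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  occ <- as.matrix(df[, -1, drop = FALSE])
  rownames(occ) <- df[[1]]
  ortholog_matrix(occ)
}

#' @rdname read_matrix_tsv
#' @param m an [ortholog_matrix()].
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(inherits(m, "ortholog_matrix"))
  df <- data.frame(strain = m$strains, m$occurrence, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Partition ortholog groups into core / moderate / rare
#'
#' Core groups are present in every strain, rare groups in exactly one strain,
#' moderately common groups in several but not all. With a single strain both
#' definitions apply and "core" takes precedence.
#'
#' @param m an [ortholog_matrix()] with at least one strain.
#' @return a `group_partition`: list of id sets `core`, `moderate`, `rare`.
#' @export
partition_groups <- function(m) {
  stopifnot(inherits(m, "ortholog_matrix"))
  n <- nrow(m$occurrence)
  if (n < 1L) stop("matrix has no strains")
  freq <- colSums(presence(m))
  structure(list(
    core = m$groups[freq == n],
    moderate = m$groups[freq > 1L & freq < n],
    rare = if (n == 1L) character(0) else m$groups[freq == 1L]
  ), class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat(sprintf("group_partition: core %d, moderate %d, rare %d\n",
              length(x$core), length(x$moderate), length(x$rare)))
  invisible(x)
}

#' Shared-ortholog matrix and complete-linkage tree
#'
#' Counts groups shared (binary presence) by every strain pair; the diagonal
#' holds per-strain group counts. The accompanying tree is complete-linkage
#' hierarchical clustering on distance `max(shared) - shared`, serialized as
#' Newick with branch lengths from the linkage heights.
#'
#' Paralog multiplicity does not enter the shared counts: presence is binary.
#'
#' @param m an [ortholog_matrix()].
#' @return list with `shared` (symmetric integer matrix), `tree` (an
#'   [ape::phylo] or `NULL` when fewer than 2 strains... with one strain the
#'   matrix is still returned), `newick` (character or `NA`).
#' @export
shared_matrix <- function(m) {
  stopifnot(inherits(m, "ortholog_matrix"))
  p <- presence(m)
  sh <- tcrossprod(p)
  storage.mode(sh) <- "integer"
  if (nrow(sh) < 2L)
    return(list(shared = sh, tree = NULL, newick = NA_character_))
  d <- stats::as.dist(max(sh) - sh)
  hc <- stats::hclust(d, method = "complete")
  tree <- ape::as.phylo(hc)
  list(shared = sh, tree = tree, newick = ape::write.tree(tree))
}
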