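# Readers and writers for the pipeline's external formats. All tables are
# UTF-8 TSV; writers prepend a comment line naming the tool version. Gene
# identifiers are opaque case-sensitive strings; no ID mapping is attempted.

.versionHeader <- function() {
  sprintf("# obkit %s", as.character(packageVersion("obkit")))
}

.writeTsv <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.versionHeader(), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TPM expression table
#'
#' Parses a TSV with a header row of sample identifiers and gene
#' identifiers in the first column into a
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with a single `tpm` assay; each sample is labelled with its group (cell
#' type or developmental stage) via `colData(se)$group`.
#'
#' @param path TSV file; first column gene ids, remaining columns TPM.
#' @param groupMap named character vector mapping every sample id to its
#'   group label.
#' @return a `SummarizedExperiment` with assay `tpm` and column data
#'   `group`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t1.0\t2.0", "g2\t0.5\t0"), tf)
#' se <- readExpression(tf, c(s1 = "early", s2 = "late"))
#' SummarizedExperiment::assay(se, "tpm")
#' @export
readExpression <- function(path, groupMap) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs gene ids plus >=1 sample")
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid TPM at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  rownames(mat) <- genes
  samples <- colnames(mat)
  if (is.null(names(groupMap)) || !all(samples %in% names(groupMap)))
    stop("every sample needs exactly one group label in groupMap")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = mat),
    colData = S4Vectors::DataFrame(group = unname(groupMap[samples]),
                                   row.names = samples))
}

#' @rdname readExpression
#' @param se a `SummarizedExperiment` with a `tpm` assay.
#' @export
writeExpression <- function(se, path) {
  mat <- SummarizedExperiment::assay(se, "tpm")
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTsv(df, path)
}

#' Read a weighted edge list
#'
#' Parses a STRING-style three-column table (id, id, combined confidence
#' score) into an undirected edge table with scores normalized to the unit
#' scale. Self-edges are dropped (with a message reporting the count) and
#' duplicate undirected pairs are collapsed keeping the maximum score, so
#' the result is order-insensitive in the input rows.
#'
#' @param path whitespace- or tab-separated file with >= 3 columns; a
#'   header line is tolerated and skipped.
#' @param scoreScale `"auto"` (default), `"unit"`, or `"thousand"`.
#'   `"thousand"` divides scores by 1000 (the STRING integer convention);
#'   `"auto"` selects `"thousand"` iff any score exceeds 1, since
#'   unit-scale scores cannot.
#' @return data.frame with columns `gene_a`, `gene_b`, `score`
#'   (`score` in (0, 1]).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("A B 400", "B A 700", "A C 900"), tf)
#' readEdges(tf)   # A-B collapsed to 0.7
#' @export
readEdges <- function(path, scoreScale = c("auto", "unit", "thousand")) {
  scoreScale <- match.arg(scoreScale)
  tab <- tryCatch(
    read.table(path, header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse edge table: ",
                             conditionMessage(e)))
  if (ncol(tab) < 3) stop("edge table needs at least 3 columns")
  # tolerate a header row of column names
  if (is.character(tab[[3]]) && is.na(suppressWarnings(as.numeric(tab[1, 3]))))
    tab <- tab[-1, , drop = FALSE]
  a <- as.character(tab[[1]]); b <- as.character(tab[[2]])
  s <- suppressWarnings(as.numeric(tab[[3]]))
  if (any(is.na(s))) stop("non-numeric score in edge table")
  if (any(s <= 0)) stop("scores must be positive")
  if (scoreScale == "auto")
    scoreScale <- if (any(s > 1)) "thousand" else "unit"
  if (scoreScale == "thousand") s <- s / 1000
  if (any(s > 1)) stop("scores exceed 1 after normalization")
  loops <- a == b
  if (any(loops)) {
    message(sum(loops), " self-edge(s) dropped")
    a <- a[!loops]; b <- b[!loops]; s <- s[!loops]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  smax <- vapply(split(s, key), max, numeric(1))
  out <- data.frame(gene_a = lo[keep], gene_b = hi[keep],
                    score = unname(smax[key[keep]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname readEdges
#' @param edges data.frame as returned by `readEdges()`.
#' @export
writeEdges <- function(edges, path) {
  .writeTsv(edges[, c("gene_a", "gene_b", "score")], path)
}

#' Read an OrthoFinder-style orthogroup table
#'
#' Parses the `Orthogroups.tsv` dialect — first column the orthogroup id,
#' one column per species holding a comma-separated gene list, empty cells
#' allowed — into a long-format table. Within one species a gene may belong
#' to at most one orthogroup.
#'
#' @param path TSV file in the `Orthogroups.tsv` layout.
#' @param speciesIds species identifiers, in the column order of the file;
#'   `NULL` takes them from the header.
#' @return data.frame with columns `orthogroup`, `species`, `gene` (one row
#'   per gene membership; empty cells contribute no rows).
#' @export
readOrthogroups <- function(path, speciesIds = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("orthogroup table needs an id column plus species")
  if (is.null(speciesIds)) speciesIds <- colnames(tab)[-1]
  if (length(speciesIds) != ncol(tab) - 1)
    stop("speciesIds must match the species columns")
  og <- as.character(tab[[1]])
  rows <- vector("list", length(speciesIds))
  for (j in seq_along(speciesIds)) {
    cells <- tab[[j + 1]]
    genes <- lapply(cells, function(x) {
      x <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
      x[nzchar(x)]
    })
    n <- lengths(genes)
    rows[[j]] <- data.frame(orthogroup = rep(og, n),
                            species = speciesIds[j],
                            gene = unlist(genes, use.names = FALSE),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  dup <- duplicated(out[, c("species", "gene")])
  if (any(dup))
    stop("gene '", out$gene[dup][1], "' of species '", out$species[dup][1],
         "' appears in more than one orthogroup")
  rownames(out) <- NULL
  out
}

#' @rdname readOrthogroups
#' @param og long-format orthogroup data.frame (`orthogroup`, `species`,
#'   `gene`).
#' @export
writeOrthogroups <- function(og, path) {
  species <- sort(unique(og$species))
  ids <- sort(unique(og$orthogroup))
  wide <- data.frame(Orthogroup = ids, stringsAsFactors = FALSE)
  for (sp in species) {
    sub <- og[og$species == sp, , drop = FALSE]
    cells <- vapply(ids, function(i)
      paste(sort(sub$gene[sub$orthogroup == i]), collapse = ","),
      character(1))
    wide[[sp]] <- unname(cells)
  }
  .writeTsv(wide, path)
}

#' Read a gene set
#'
#' Reads one gene identifier per line (first column of each line),
#' trimming whitespace and de-duplicating. An empty file yields an empty
#' set with a warning.
#'
#' @param path text file with gene ids in the first column.
#' @param label name attached to the set (attribute `label`).
#' @return character vector of unique gene ids with a `label` attribute.
#' @export
readGeneSet <- function(path, label = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  ids <- trimws(vapply(strsplit(lines, "\t"), function(x)
    if (length(x)) x[1] else "", character(1)))
  ids <- unique(ids[nzchar(ids)])
  if (!length(ids)) warning("gene set '", label, "' is empty")
  structure(ids, label = label)
}

#' @rdname readGeneSet
#' @param genes character vector of gene ids.
#' @export
writeGeneSet <- function(genes, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.versionHeader(), con)
  writeLines(unique(as.character(genes)), con)
  invisible(path)
}

#' Write a layer or backbone as TSV
#'
#' Serializes a [Layer-class] as an edge table (`gene_a`, `gene_b`,
#' `score`, `distance`; plus `metric` for a [BackboneResult-class]) and,
#' optionally, a node-attribute table (`gene`, `conserved`).
#'
#' @param x a `Layer` or `BackboneResult`.
#' @param path output TSV for the edge table.
#' @param nodePath optional output TSV for node attributes.
#' @return `path`, invisibly.
#' @export
writeLayer <- function(x, path, nodePath = NULL) {
  .writeTsv(edgeTable(x), path)
  if (!is.null(nodePath)) {
    lay <- if (is(x, "BackboneResult")) x@layer else x
    flags <- conservedNodes(lay)
    .writeTsv(data.frame(gene = names(flags), conserved = unname(flags),
                         stringsAsFactors = FALSE), nodePath)
  }
  invisible(path)
}
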