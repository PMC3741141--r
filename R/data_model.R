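#' Construct a phenotype time-course dataset
#'
#' A `pheno_dataset` holds per-gene, per-phenotype score vectors over a fixed
#' number of time points: the gene x phenotype x time value tensor that every
#' downstream operation (gating, connection derivation, networks, rendering)
#' consumes. Not every (gene, phenotype) pair needs to be observed; values of
#' observed pairs may still contain `NA` for individual time points. Time
#' points are indexed 1..n throughout the package.
#'
#' @param pairs data.frame with character columns `gene` and `phenotype`, one
#'   row per observed pair, in file/input order (first occurrence defines gene
#'   and phenotype ordering).
#' @param values numeric matrix with one row per row of `pairs` and
#'   `n_timepoints` columns; `NA` marks a missing score.
#' @return An object of class `pheno_dataset` with elements `genes`,
#'   `phenotypes`, `n_timepoints`, `values` (3-d array gene x phenotype x
#'   time, `NA` where a pair is unobserved or a score is missing), `observed`
#'   (logical gene x phenotype matrix) and `pairs` (the input pair table).
#' @export
pheno_dataset <- function(pairs, values) {
  if (!is.data.frame(pairs) || !all(c("gene", "phenotype") %in% names(pairs)))
    abort_value("`pairs` must be a data.frame with columns gene, phenotype")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(pairs))
    abort_value("`values` must have one row per (gene, phenotype) pair")
  if (ncol(values) < 1L)
    abort_value("at least one time point is required")
  key <- paste(pairs$gene, pairs$phenotype, sep = "\r")
  if (anyDuplicated(key)) {
    d <- pairs[duplicated(key), , drop = FALSE][1L, ]
    abort_duplicate(sprintf("duplicate (gene, phenotype) record: (%s, %s)",
                            d$gene, d$phenotype))
  }
  genes <- unique(as.character(pairs$gene))
  phenotypes <- unique(as.character(pairs$phenotype))
  n <- ncol(values)
  arr <- array(NA_real_, dim = c(length(genes), length(phenotypes), n),
               dimnames = list(gene = genes, phenotype = phenotypes,
                               time = as.character(seq_len(n))))
  obs <- matrix(FALSE, length(genes), length(phenotypes),
                dimnames = list(genes, phenotypes))
  gi <- match(pairs$gene, genes)
  pi_ <- match(pairs$phenotype, phenotypes)
  for (r in seq_len(nrow(pairs))) {
    arr[gi[r], pi_[r], ] <- values[r, ]
    obs[gi[r], pi_[r]] <- TRUE
  }
  structure(list(
    genes = genes, phenotypes = phenotypes, n_timepoints = n,
    values = arr, observed = obs,
    pairs = data.frame(gene = as.character(pairs$gene),
                       phenotype = as.character(pairs$phenotype),
                       stringsAsFactors = FALSE)
  ), class = "pheno_dataset")
}

#' @export
print.pheno_dataset <- function(x, ...) {
  cat(sprintf("pheno_dataset: %d genes x %d phenotypes x %d time points (%d records)\n",
              length(x$genes), length(x$phenotypes), x$n_timepoints,
              nrow(x$pairs)))
  invisible(x)
}

#' Parse the whitespace-delimited dataset format
#'
#' Each row is `<gene> <phenotype> <v1> ... <vn>`: gene name, phenotype
#' label, then one score per time point, separated by runs of spaces or tabs.
#' The number of time points is the field count minus two and must be the
#' same on every row. Row order defines gene and phenotype ordering (first
#' occurrence wins). A value equal to `missing_token` is stored as `NA`.
#'
#' @param text character scalar (the file contents) or character vector of
#'   lines. Blank lines are ignored.
#' @param missing_token token marking a missing score (default `"NA"`).
#' @return A [pheno_dataset].
#' @export
parse_dataset <- function(text, missing_token = "NA") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) abort_format("empty dataset: no data rows")
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    abort_format(sprintf("line %d has %d fields; at least 3 required (gene, phenotype, value...)",
                         lineno[which(nf < 3L)[1L]], nf[which(nf < 3L)[1L]]))
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    abort_format(sprintf("ragged row: line %d has %d fields but line %d has %d",
                         lineno[bad], nf[bad], lineno[1L], nf[1L]))
  }
  m <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  raw <- m[, -(1:2), drop = FALSE]
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) & raw != missing_token, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    abort_value(sprintf("non-numeric value '%s' at line %d, time point %d",
                        raw[bad[1L, 1L], bad[1L, 2L]], lineno[bad[1L, 1L]],
                        bad[1L, 2L]))
  vals[raw == missing_token] <- NA_real_
  pheno_dataset(data.frame(gene = m[, 1L], phenotype = m[, 2L],
                           stringsAsFactors = FALSE), vals)
}

#' Serialize a dataset back to the whitespace-delimited format
#'
#' Records are written in stored pair order, so
#' `parse_dataset(write_dataset(d))` reproduces `d` field for field.
#'
#' @param dataset a [pheno_dataset].
#' @param missing_token token written for `NA` scores.
#' @return character scalar (rows joined by newlines, trailing newline).
#' @export
write_dataset <- function(dataset, missing_token = "NA") {
  stopifnot(inherits(dataset, "pheno_dataset"))
  rows <- vapply(seq_len(nrow(dataset$pairs)), function(r) {
    g <- dataset$pairs$gene[r]; p <- dataset$pairs$phenotype[r]
    v <- dataset$values[g, p, ]
    vs <- ifelse(is.na(v), missing_token,
                 vapply(v, format_num, character(1)))
    paste(c(g, p, vs), collapse = " ")
  }, character(1))
  paste0(paste(rows, collapse = "\n"), "\n")
}

# %.15g keeps round-trips exact for doubles generated at fixture precision
format_num <- function(x) formatC(x, format = "g", digits = 15)

#' Parse annotation (e.g. GO enrichment) network files
#'
#' Two companion files describe an annotation network: an enrichment table
#' with four tab-separated columns (term id, description, enrichment
#' p-value, "|"-separated member gene list) and an interaction file with one
#' tab-separated term-id pair per line. Interaction rows referencing a term
#' absent from the enrichment table are dropped with a warning.
#'
#' @param enrichment_text,interaction_text character scalars or line vectors;
#'   `interaction_text` may be empty/`NULL` for an edgeless network.
#' @return An object of class `annotation_network`: `terms` (data.frame with
#'   columns id, description, p_value and list-column members) and `edges`
#'   (data.frame from, to).
#' @export
parse_annotation_network <- function(enrichment_text, interaction_text = NULL) {
  elines <- split_lines(enrichment_text)
  if (length(elines) == 0L) abort_format("empty enrichment table")
  parts <- strsplit(elines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    abort_format(sprintf(
      "enrichment line %d has %d tab-separated fields; 4 required",
      which(lengths(parts) != 4L)[1L], lengths(parts)[which(lengths(parts) != 4L)[1L]]))
  em <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  p <- suppressWarnings(as.numeric(em[, 3L]))
  if (anyNA(p) || any(p < 0 | p > 1))
    abort_value(sprintf("enrichment p-value '%s' is not in [0, 1]",
                        em[which(is.na(p) | p < 0 | p > 1)[1L], 3L]))
  members <- strsplit(em[, 4L], "|", fixed = TRUE)
  if (any(lengths(members) == 0L) || any(vapply(members, function(x) any(!nzchar(x)), logical(1))))
    abort_value("every term needs a non-empty member gene list")
  terms <- data.frame(id = em[, 1L], description = em[, 2L], p_value = p,
                      stringsAsFactors = FALSE)
  terms$members <- members
  edges <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  ilines <- split_lines(interaction_text)
  if (length(ilines) > 0L) {
    ip <- strsplit(ilines, "\t", fixed = TRUE)
    if (any(lengths(ip) != 2L))
      abort_format(sprintf("interaction line %d does not have 2 tab-separated fields",
                           which(lengths(ip) != 2L)[1L]))
    im <- matrix(unlist(ip), ncol = 2L, byrow = TRUE)
    known <- im[, 1L] %in% terms$id & im[, 2L] %in% terms$id
    if (any(!known)) {
      for (r in which(!known))
        warning(sprintf("dropping interaction %s -- %s: unknown term",
                        im[r, 1L], im[r, 2L]), call. = FALSE)
      im <- im[known, , drop = FALSE]
    }
    edges <- data.frame(from = im[, 1L], to = im[, 2L],
                        stringsAsFactors = FALSE)
  }
  structure(list(terms = terms, edges = edges),
            class = "annotation_network")
}

split_lines <- function(text) {
  if (is.null(text)) return(character(0))
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines[nzchar(trimws(lines))]
}

#' Parse a bar-chart series (one value per time point)
#'
#' @param text whitespace-separated numbers, one per time point.
#' @param n_timepoints expected length (from the companion dataset).
#' @param label display label for the series.
#' @return An object of class `bar_series`: list(label, values).
#' @export
parse_barseries <- function(text, n_timepoints, label = "bars") {
  toks <- unlist(strsplit(trimws(paste(text, collapse = " ")), "[ \t\n]+"))
  toks <- toks[nzchar(toks)]
  v <- suppressWarnings(as.numeric(toks))
  if (anyNA(v))
    abort_value(sprintf("non-numeric bar value '%s'", toks[which(is.na(v))[1L]]))
  if (length(v) != n_timepoints)
    abort_format(sprintf("bar series has %d values but the dataset has %d time points",
                         length(v), n_timepoints))
  structure(list(label = label, values = v), class = "bar_series")
}

#' Write a connection set as TSV
#'
#' Columns: source, target, t_source, t_target, weight, genes (the gene set
#' "|"-joined in lexicographic order). An empty set yields a header-only
#' table.
#'
#' @param connections a [connection_set].
#' @return character scalar of TSV text.
#' @export
write_connections_tsv <- function(connections) {
  stopifnot(inherits(connections, "connection_set"))
  header <- "source\ttarget\tt_source\tt_target\tweight\tgenes"
  if (nrow(connections) == 0L) return(paste0(header, "\n"))
  rows <- vapply(seq_len(nrow(connections)), function(r) {
    paste(connections$source[r], connections$target[r],
          connections$t_source[r], connections$t_target[r],
          connections$weight[r],
          paste(sort(connections$genes[[r]]), collapse = "|"),
          sep = "\t")
  }, character(1))
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' Write a gene network edge list as TSV
#'
#' One `from<TAB>to<TAB>weight` line per edge, endpoints sorted within each
#' line and lines sorted, so output is canonical for a given edge set.
#'
#' @param network a [gene_network].
#' @return character scalar of TSV text (no header, matching the interaction
#'   file dialect).
#' @export
write_edge_list <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  e <- network$edges
  if (nrow(e) == 0L) return("")
  a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
  lines <- paste(a, b, e$weight, sep = "\t")
  paste0(paste(sort(lines), collapse = "\n"), "\n")
}

#' Write node annotations (role, first phenotype) as TSV
#'
#' @param network a [gene_network].
#' @return character scalar with header `gene  role  first_phenotype`.
#' @export
write_node_table <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  n <- network$nodes
  header <- "gene\trole\tfirst_phenotype"
  if (nrow(n) == 0L) return(paste0(header, "\n"))
  o <- order(n$gene)
  rows <- paste(n$gene[o],
                ifelse(is.na(n$role[o]), ".", n$role[o]),
                ifelse(is.na(n$first_phenotype[o]), ".", n$first_phenotype[o]),
                sep = "\t")
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}
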