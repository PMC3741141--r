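#' Per-phenotype threshold intervals
#'
#' A threshold spec assigns each phenotype an inclusive interval `[lo, hi]`
#' in score units; scores inside the interval count as events. Phenotypes
#' without an explicit interval get `(-Inf, Inf)`, i.e. every observed score
#' passes — with no thresholds all phenotypes end up interconnected, which
#' is why gating matters for real screens.
#'
#' @param phenotypes character vector of phenotype labels (usually
#'   `dataset$phenotypes`).
#' @param intervals named list, `phenotype = c(lo, hi)`.
#' @return numeric matrix with rownames `phenotypes` and columns `lo`, `hi`,
#'   of class `threshold_spec`.
#' @export
threshold_spec <- function(phenotypes, intervals = list()) {
  unknown <- setdiff(names(intervals), phenotypes)
  if (length(unknown) > 0L)
    abort_key(sprintf("threshold for unknown phenotype: %s", unknown[1L]))
  m <- matrix(c(-Inf, Inf), nrow = length(phenotypes), ncol = 2L,
              byrow = TRUE, dimnames = list(phenotypes, c("lo", "hi")))
  for (p in names(intervals)) {
    iv <- intervals[[p]]
    if (length(iv) != 2L || anyNA(iv))
      abort_value(sprintf("interval for '%s' must be c(lo, hi)", p))
    if (iv[1L] > iv[2L])
      abort_value(sprintf("interval for '%s' has lo > hi", p))
    m[p, ] <- iv
  }
  class(m) <- c("threshold_spec", class(m))
  m
}

as_threshold_spec <- function(thresholds, phenotypes) {
  if (is.null(thresholds)) return(threshold_spec(phenotypes))
  if (inherits(thresholds, "threshold_spec")) {
    if (!setequal(rownames(thresholds), phenotypes) &&
        length(setdiff(rownames(thresholds), phenotypes)) > 0L)
      abort_key(sprintf("threshold for unknown phenotype: %s",
                        setdiff(rownames(thresholds), phenotypes)[1L]))
    full <- threshold_spec(phenotypes)
    full[rownames(thresholds), ] <- thresholds
    return(full)
  }
  threshold_spec(phenotypes, thresholds)
}

#' Gate events: which (gene, phenotype, time) scores pass their thresholds
#'
#' @param dataset a [pheno_dataset].
#' @param thresholds `NULL` (all observed scores pass), a [threshold_spec],
#'   or a named list of `c(lo, hi)` intervals. Intervals are inclusive at
#'   both ends. Missing scores never pass.
#' @return logical gene x phenotype x time array (an event mask).
#' @export
build_mask <- function(dataset, thresholds = NULL) {
  stopifnot(inherits(dataset, "pheno_dataset"))
  th <- as_threshold_spec(thresholds, dataset$phenotypes)
  v <- dataset$values
  lo <- th[dataset$phenotypes, "lo"]
  hi <- th[dataset$phenotypes, "hi"]
  mask <- array(FALSE, dim = dim(v), dimnames = dimnames(v))
  for (p in seq_along(dataset$phenotypes)) {
    vp <- v[, p, , drop = FALSE]
    mask[, p, ] <- !is.na(vp) & vp >= lo[p] & vp <= hi[p]
  }
  mask
}

#' Quartile-gating thresholds (lower/upper quartile of pooled scores)
#'
#' Pools each phenotype's non-missing scores across all genes and time
#' points and derives the interval that keeps the lower quartile
#' (`(-Inf, Q1]`) or the upper quartile (`[Q3, +Inf)`). Quartiles use the
#' linear-interpolation percentile definition (rank `0.25 * (n - 1)` between
#' order statistics; `stats::quantile` type 7).
#'
#' @param dataset a [pheno_dataset].
#' @param side `"lower"` or `"upper"`.
#' @return a [threshold_spec] covering every phenotype of the dataset.
#' @export
quartile_thresholds <- function(dataset, side = c("lower", "upper")) {
  stopifnot(inherits(dataset, "pheno_dataset"))
  side <- match.arg(side)
  intervals <- lapply(dataset$phenotypes, function(p) {
    obs <- dataset$values[, p, ]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0L)
      abort_value(sprintf("phenotype '%s' has no observed values", p))
    if (side == "lower")
      c(-Inf, unname(stats::quantile(obs, 0.25, type = 7)))
    else
      c(unname(stats::quantile(obs, 0.75, type = 7)), Inf)
  })
  names(intervals) <- dataset$phenotypes
  threshold_spec(dataset$phenotypes, intervals)
}

#' Construct a connection set
#'
#' Connections are the arcs: weighted, timed links between two phenotypes,
#' each carrying the set of genes that produce it. `weight` is always the
#' size of the gene set; empty connections are never stored. Lag-0 records
#' are undirected and stored with endpoints in dataset phenotype order;
#' records with positive lag are directed source -> target.
#'
#' @param source,target phenotype labels.
#' @param t_source,t_target 1-based time indices, `t_target >= t_source`.
#' @param genes list of character vectors (one gene set per record).
#' @param directed logical vector.
#' @return data.frame of class `connection_set` with columns source, target,
#'   t_source, t_target, genes (list-column), weight, directed.
#' @export
connection_set <- function(source = character(0), target = character(0),
                           t_source = integer(0), t_target = integer(0),
                           genes = list(), directed = logical(0)) {
  if (any(t_target < t_source))
    abort_value("t_target must be >= t_source")
  if (any(lengths(genes) == 0L))
    abort_value("empty gene sets are never stored")
  df <- data.frame(source = as.character(source),
                   target = as.character(target),
                   t_source = as.integer(t_source),
                   t_target = as.integer(t_target),
                   weight = lengths(genes),
                   directed = as.logical(directed),
                   stringsAsFactors = FALSE)
  df$genes <- lapply(genes, as.character)
  df <- df[, c("source", "target", "t_source", "t_target", "genes",
               "weight", "directed")]
  class(df) <- c("connection_set", "data.frame")
  df
}

#' @export
print.connection_set <- function(x, ...) {
  cat(sprintf("connection_set: %d records, total weight %d\n",
              nrow(x), sum(x$weight)))
  invisible(x)
}

#' Derive lagged co-occurrence connections from an event mask
#'
#' For each gene, pair of distinct phenotypes `(p, q)`, time `t` and lag
#' `x` in `lags` with `t + x <= n`: the gene joins the connection
#' `(p, q, t, t + x)` whenever its mask is true for `p` at `t` and for `q`
#' at `t + x`. Lag-0 connections are undirected (each unordered pair counted
#' once, endpoints in phenotype order); positive lags give directed
#' connections. Weights count genes per `(p, q, t, lag)` record.
#'
#' @param mask logical gene x phenotype x time array from [build_mask()].
#' @param lags integer vector of exact lags, each in `0..(n - 1)`.
#' @return a [connection_set].
#' @export
derive_cooccurrence <- function(mask, lags = 0L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  n <- dim(mask)[3L]
  phen <- dimnames(mask)[[2L]]
  genes <- dimnames(mask)[[1L]]
  lags <- as.integer(lags)
  if (any(lags < 0L | lags > n - 1L))
    abort_value(sprintf("lag out of range 0..%d", n - 1L))
  recs <- list()
  for (x in sort(unique(lags))) {
    for (t in seq_len(n - x)) {
      A <- matrix(mask[, , t], nrow = length(genes))
      B <- matrix(mask[, , t + x], nrow = length(genes))
      for (p in seq_along(phen)) {
        qs <- if (x == 0L) seq_along(phen)[-seq_len(p)] else
          seq_along(phen)[-p]
        for (q in qs) {
          g <- genes[A[, p] & B[, q]]
          if (length(g) > 0L)
            recs[[length(recs) + 1L]] <- list(
              source = phen[p], target = phen[q],
              t_source = t, t_target = t + x,
              genes = g, directed = x > 0L)
        }
      }
    }
  }
  bind_connection_records(recs)
}

bind_connection_records <- function(recs) {
  if (length(recs) == 0L) return(connection_set())
  connection_set(
    source = vapply(recs, `[[`, character(1), "source"),
    target = vapply(recs, `[[`, character(1), "target"),
    t_source = vapply(recs, `[[`, numeric(1), "t_source"),
    t_target = vapply(recs, `[[`, numeric(1), "t_target"),
    genes = lapply(recs, `[[`, "genes"),
    directed = vapply(recs, `[[`, logical(1), "directed"))
}

#' Most prominent phenotype per gene and time point
#'
#' The prominence profile records, for every gene and time point, the
#' phenotype with the maximal score for that gene's perturbation — optionally
#' restricted to scores passing thresholds. Ties are broken by phenotype
#' input order (first wins). The entry is `NA` when no score is present
#' (or none passes the thresholds) at that time.
#'
#' @param dataset a [pheno_dataset].
#' @param thresholds optional gating as in [build_mask()].
#' @return character gene x time matrix of phenotype labels (or `NA`), of
#'   class `prominence_profile`, with the phenotype universe attached as
#'   attribute `phenotypes`.
#' @export
derive_prominence <- function(dataset, thresholds = NULL) {
  stopifnot(inherits(dataset, "pheno_dataset"))
  mask <- build_mask(dataset, thresholds)
  v <- dataset$values
  v[!mask] <- NA_real_
  prof <- matrix(NA_character_, length(dataset$genes), dataset$n_timepoints,
                 dimnames = list(dataset$genes,
                                 as.character(seq_len(dataset$n_timepoints))))
  for (t in seq_len(dataset$n_timepoints)) {
    vt <- matrix(v[, , t], nrow = length(dataset$genes))
    ok <- rowSums(!is.na(vt)) > 0L
    if (any(ok)) {
      idx <- apply(vt[ok, , drop = FALSE], 1L, which.max)
      prof[ok, t] <- dataset$phenotypes[idx]
    }
  }
  structure(prof, phenotypes = dataset$phenotypes,
            class = c("prominence_profile", class(prof)))
}

#' Phenotype transitions between consecutive time points
#'
#' An arc is a transition of a gene's prominent phenotype between
#' consecutive time points: for each gene and each `t` where both
#' `profile[t]` and `profile[t + 1]` are present and differ, the gene joins
#' the directed connection `(p_t, p_{t+1}, t, t + 1)`. A gap (`NA`) breaks
#' the chain — no arc is emitted across it. The display color of a
#' transition arc is keyed to the target phenotype (the phenotype the cells
#' transition into).
#'
#' @param profile a `prominence_profile` from [derive_prominence()].
#' @param include_self also emit records where the phenotype is unchanged
#'   (default `FALSE`).
#' @return a [connection_set] of directed lag-1 records.
#' @export
derive_transitions <- function(profile, include_self = FALSE) {
  stopifnot(inherits(profile, "prominence_profile"))
  n <- ncol(profile)
  recs <- list()
  if (n >= 2L) {
    for (t in seq_len(n - 1L)) {
      a <- profile[, t]; b <- profile[, t + 1L]
      sel <- !is.na(a) & !is.na(b) & (include_self | a != b)
      if (!any(sel)) next
      key <- paste(a[sel], b[sel], sep = "\r")
      for (k in unique(key)) {
        g <- rownames(profile)[sel][key == k]
        pq <- strsplit(k, "\r", fixed = TRUE)[[1L]]
        recs[[length(recs) + 1L]] <- list(
          source = pq[1L], target = pq[2L],
          t_source = t, t_target = t + 1L,
          genes = g, directed = TRUE)
      }
    }
  }
  bind_connection_records(recs)
}

#' Filter a connection set by genes, phenotypes, time window or lag
#'
#' Gene filtering intersects each record's gene set with `gene_subset` and
#' drops records that become empty (weights are recomputed). Phenotype
#' filtering uses touch semantics: a record is kept if either endpoint is in
#' `phenotype_subset`. The time window keeps records with both `t_source`
#' and `t_target` inside `[time_window[1], time_window[2]]`; `max_lag` keeps
#' records with `t_target - t_source <= max_lag`.
#'
#' @param connections a [connection_set].
#' @param gene_subset,phenotype_subset optional character vectors.
#' @param time_window optional `c(first, last)` 1-based time bounds.
#' @param max_lag optional non-negative integer.
#' @param dataset optional [pheno_dataset]; when given, subset names are
#'   validated against it and unknown names raise a key error.
#' @return the filtered [connection_set].
#' @export
filter_connections <- function(connections, gene_subset = NULL,
                               phenotype_subset = NULL, time_window = NULL,
                               max_lag = NULL, dataset = NULL) {
  stopifnot(inherits(connections, "connection_set"))
  if (!is.null(dataset)) {
    if (!is.null(gene_subset) && length(setdiff(gene_subset, dataset$genes)))
      abort_key(sprintf("unknown gene: %s",
                        setdiff(gene_subset, dataset$genes)[1L]))
    if (!is.null(phenotype_subset) &&
        length(setdiff(phenotype_subset, dataset$phenotypes)))
      abort_key(sprintf("unknown phenotype: %s",
                        setdiff(phenotype_subset, dataset$phenotypes)[1L]))
  }
  keep <- rep(TRUE, nrow(connections))
  if (!is.null(phenotype_subset))
    keep <- keep & (connections$source %in% phenotype_subset |
                    connections$target %in% phenotype_subset)
  if (!is.null(time_window))
    keep <- keep & connections$t_source >= time_window[1L] &
      connections$t_target <= time_window[2L]
  if (!is.null(max_lag))
    keep <- keep & (connections$t_target - connections$t_source) <= max_lag
  out <- connections[keep, , drop = FALSE]
  if (!is.null(gene_subset) && nrow(out) > 0L) {
    out$genes <- lapply(out$genes, intersect, y = gene_subset)
    out$weight <- lengths(out$genes)
    out <- out[out$weight > 0L, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("connection_set", "data.frame")
  out
}

#' Genes specific to a single phenotype pair
#'
#' For each unordered phenotype pair in scope (all records, or only those
#' with `t_source == t`), returns the genes that appear in that pair's
#' pooled gene set and in no other pair's — the pair-specific genes one
#' would circle next to a link.
#'
#' @param connections a non-empty [connection_set].
#' @param t optional 1-based time point restricting the scope.
#' @return named list mapping `"p|q"` (endpoints sorted) to a character
#'   vector of specific genes (possibly empty).
#' @export
pair_specific_genes <- function(connections, t = NULL) {
  stopifnot(inherits(connections, "connection_set"))
  if (nrow(connections) == 0L) abort_value("connection set is empty")
  sub <- if (is.null(t)) connections else
    connections[connections$t_source == t, , drop = FALSE]
  if (nrow(sub) == 0L) return(stats::setNames(list(), character(0)))
  pair <- paste(pmin(sub$source, sub$target),
                pmax(sub$source, sub$target), sep = "|")
  pooled <- lapply(split(sub$genes, pair),
                   function(gs) sort(unique(unlist(gs))))
  lapply(stats::setNames(names(pooled), names(pooled)), function(k) {
    others <- unique(unlist(pooled[setdiff(names(pooled), k)]))
    setdiff(pooled[[k]], others)
  })
}
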