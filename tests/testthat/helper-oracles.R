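# Independent reference implementations (brute force / enumeration) used as
# oracles against the package's optimized paths, plus small input builders.

# random fully-parameterized valid dataset for round-trip properties
random_dataset <- function(n_genes = 5, n_phen = 3, n_time = 4,
                           p_missing = 0.1, complete_pairs = FALSE) {
  genes <- sprintf("gene%02d", seq_len(n_genes))
  phen <- sprintf("ph%d", seq_len(n_phen))
  pairs <- expand.grid(gene = genes, phenotype = phen,
                       stringsAsFactors = FALSE)
  pairs <- pairs[order(match(pairs$gene, genes)), ]
  if (!complete_pairs) {
    keep <- runif(nrow(pairs)) > 0.2
    keep[sample.int(nrow(pairs), 1L)] <- TRUE
    pairs <- pairs[keep, , drop = FALSE]
  }
  vals <- matrix(round(runif(nrow(pairs) * n_time), 6), nrow(pairs), n_time)
  vals[runif(length(vals)) < p_missing] <- NA_real_
  pheno_dataset(pairs, vals)
}

# dataset from an explicit gene x time profile matrix of prominent
# phenotypes: prominent scores 0.9, background 0.1
dataset_from_profiles <- function(prof, phenotypes) {
  genes <- rownames(prof)
  pairs <- expand.grid(gene = genes, phenotype = phenotypes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[order(match(pairs$gene, genes)), ]
  vals <- matrix(0.1, nrow(pairs), ncol(prof))
  for (r in seq_len(nrow(pairs))) {
    g <- pairs$gene[r]; p <- pairs$phenotype[r]
    hit <- !is.na(prof[g, ]) & prof[g, ] == p
    vals[r, hit] <- 0.9
    vals[r, is.na(prof[g, ])] <- NA_real_
  }
  pheno_dataset(pairs, vals)
}

# triple-loop recount of lagged co-occurrence weights
brute_cooccurrence <- function(mask, lags) {
  n <- dim(mask)[3L]
  genes <- dimnames(mask)[[1L]]
  phen <- dimnames(mask)[[2L]]
  counts <- new.env(parent = emptyenv())
  for (g in genes) for (x in lags) for (t in seq_len(n - x)) {
    for (pi in seq_along(phen)) for (qi in seq_along(phen)) {
      if (pi == qi) next
      if (x == 0L && qi < pi) next
      if (mask[g, pi, t] && mask[g, qi, t + x]) {
        key <- paste(phen[pi], phen[qi], t, t + x, sep = "\r")
        counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      }
    }
  }
  out <- as.list(counts)
  data.frame(key = names(out), weight = unlist(out),
             stringsAsFactors = FALSE, row.names = NULL)
}

connections_key <- function(conns) {
  stats::setNames(conns$weight,
                  paste(conns$source, conns$target, conns$t_source,
                        conns$t_target, sep = "\r"))
}

# sort-based linear-interpolation quartile: value at rank p*(n-1)
oracle_quantile <- function(v, p) {
  v <- sort(v)
  h <- p * (length(v) - 1)
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  v[lo] + (h - floor(h)) * (v[hi] - v[lo])
}

# pairwise agglomerative reference: merge heights + partition trace
ref_agglomerative <- function(m, linkage, metric) {
  pd <- as.matrix(stats::dist(m, method = metric))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- NULL; bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dd <- pd[clusters[[i]], clusters[[j]]]
      d <- switch(linkage, single = min(dd), complete = max(dd),
                  average = mean(dd))
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    clusters[[best[1L]]] <- sort(c(clusters[[best[1L]]],
                                   clusters[[best[2L]]]))
    clusters[[best[2L]]] <- NULL
    heights <- c(heights, bd)
    partitions[[length(partitions) + 1L]] <- canonical_partition(clusters)
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(clusters) {
  paste(sort(vapply(clusters, function(cl)
    paste(sort(cl), collapse = ","), character(1))), collapse = ";")
}

# partition trace implied by an hclust-style merge matrix
merge_partition_trace <- function(merges, n) {
  merged <- list()
  out <- character(0)
  for (s in seq_len(nrow(merges))) {
    get_members <- function(code)
      if (code < 0) -code else merged[[code]]
    merged[[s]] <- sort(c(get_members(merges$a[s]),
                          get_members(merges$b[s])))
    consumed <- unlist(lapply(seq_len(s), function(k)
      c(merges$a[k], merges$b[k])))
    consumed_steps <- consumed[consumed > 0]
    consumed_singletons <- -consumed[consumed < 0]
    current <- c(merged[setdiff(seq_len(s), consumed_steps)],
                 as.list(setdiff(seq_len(n), consumed_singletons)))
    out <- c(out, canonical_partition(current))
  }
  out
}

# all permutations of seq_len(n) as a matrix (n! rows)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    unname(cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }))
}

perm_score <- function(perm, W)
  sum(W[cbind(perm[-length(perm)], perm[-1L])])

exhaustive_best_score <- function(W, perms = all_perms(nrow(W)))
  max(apply(perms, 1L, perm_score, W = W))
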