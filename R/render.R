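`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rendering style
#'
#' @param palette qualitative color scheme name (a ColorBrewer qualitative
#'   scheme such as `"Set2"`, `"Dark2"` or `"Paired"` — the latter two are
#'   colorblind-safe) or `"single"` for single-color display.
#' @param transparency arc transparency in `[0, 1]` (default 0.20; drawn
#'   opacity is `1 - transparency`).
#' @param base_size unit stroke width in px per unit weight (2D arcs and
#'   chords).
#' @param unit_height unit arc apex height per unit weight (3D view).
#' @param cumulative when a time point is selected, draw all records up to
#'   it rather than only those at it.
#' @param camera `c(azimuth, elevation)` in degrees for the 3D view.
#' @param single_color color used by the `"single"` scheme and for
#'   undirected records.
#' @return list of class `style_spec`.
#' @export
style_spec <- function(palette = "Set2", transparency = 0.20,
                       base_size = 2, unit_height = 10,
                       cumulative = FALSE, camera = c(35, 25),
                       single_color = "#555555") {
  if (transparency < 0 || transparency > 1)
    abort_value("transparency must be in [0, 1]")
  if (base_size <= 0 || unit_height <= 0)
    abort_value("base sizes must be positive")
  if (any(!is.finite(camera)))
    abort_value("camera angles must be finite")
  structure(list(palette = palette, transparency = transparency,
                 base_size = base_size, unit_height = unit_height,
                 cumulative = cumulative, camera = camera,
                 single_color = single_color),
            class = "style_spec")
}

#' Qualitative color assignment for phenotypes
#'
#' @param scheme a ColorBrewer qualitative scheme name or `"single"`.
#' @param n number of colors (>= 1). For qualitative schemes `n` must not
#'   exceed the scheme capacity; switch to `"single"` for more categories.
#' @param single_color the color replicated by the `"single"` scheme.
#' @return character vector of `n` hex colors; distinct for qualitative
#'   schemes, identical for `"single"`. Assignment to phenotypes is by
#'   index, so it is stable across views.
#' @export
arc_palette <- function(scheme, n, single_color = "#555555") {
  if (n < 1L) abort_value("n must be >= 1")
  if (identical(scheme, "single")) return(rep(single_color, n))
  qual <- RColorBrewer::brewer.pal.info
  qual <- qual[qual$category == "qual", , drop = FALSE]
  if (!scheme %in% rownames(qual))
    abort_value(sprintf("unknown qualitative scheme '%s'", scheme))
  cap <- qual[scheme, "maxcolors"]
  if (n > cap)
    abort_value(sprintf(
      "scheme '%s' supports at most %d colors (need %d); use scheme 'single'",
      scheme, cap, n))
  RColorBrewer::brewer.pal(max(3L, n), scheme)[seq_len(n)]
}

# ---- SVG primitives (fixed-format numbers => byte-identical output) ----

fmt <- function(x) sprintf("%.4f", x)

svg_doc <- function(width, height, body) {
  paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" width="', width,
    '" height="', height, '" viewBox="0 0 ', width, " ", height, '">\n',
    paste(body, collapse = "\n"),
    "\n</svg>\n")
}

svg_line <- function(x1, y1, x2, y2, class, stroke, width = 1) {
  sprintf('<line class="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
          class, fmt(x1), fmt(y1), fmt(x2), fmt(y2), stroke, fmt(width))
}

svg_text <- function(x, y, label, class = "label", anchor = "end") {
  sprintf('<text class="%s" x="%s" y="%s" text-anchor="%s" font-size="11">%s</text>',
          class, fmt(x), fmt(y), anchor, label)
}

select_records <- function(connections, timepoint, cumulative) {
  if (is.null(timepoint)) return(connections)
  keep <- if (cumulative) connections$t_target <= timepoint
          else connections$t_target == timepoint
  connections[keep, , drop = FALSE]
}

record_colors <- function(connections, ordering, style) {
  pal <- arc_palette(style$palette, length(ordering), style$single_color)
  ifelse(connections$directed,
         pal[match(connections$target, ordering)],
         style$single_color)
}

#' Linear 2D arc view
#'
#' Phenotype lanes are horizontal lines (top to bottom in lane-ordering
#' order), time runs left to right with ticks 1..n, and every connection is
#' a smooth arc from (t_source, source lane) to (t_target, target lane).
#' Arc stroke width is `base_size * weight`; directed arcs take the palette
#' color of their target phenotype, undirected ones the single connection
#' color; opacity is `1 - transparency`.
#'
#' @param connections a [connection_set].
#' @param ordering phenotype lane order (must cover every phenotype
#'   appearing in `connections`).
#' @param style a [style_spec()].
#' @param timepoint optional time selection (see `cumulative` in the style).
#' @param n_timepoints time-axis extent; inferred from the records when
#'   `NULL`.
#' @return SVG text (character scalar).
#' @export
render_linear <- function(connections, ordering, style = style_spec(),
                          timepoint = NULL, n_timepoints = NULL) {
  stopifnot(inherits(connections, "connection_set"))
  used <- unique(c(connections$source, connections$target))
  if (length(setdiff(used, ordering)) > 0L)
    abort_key(sprintf("phenotype '%s' missing from ordering",
                      setdiff(used, ordering)[1L]))
  n <- n_timepoints %||% max(c(connections$t_target, 1L))
  recs <- select_records(connections, timepoint, style$cumulative)
  P <- length(ordering)
  ml <- 110; mr <- 20; mt <- 30; mb <- 30
  lane_h <- 52
  w <- 820; h <- mt + mb + lane_h * max(P - 1L, 1L) + 20
  xs <- function(t) if (n == 1L) ml + (w - ml - mr) / 2 else
    ml + (t - 1) / (n - 1) * (w - ml - mr)
  ys <- function(p) mt + 10 + (match(p, ordering) - 1L) * lane_h
  body <- character(0)
  for (p in ordering) {
    body <- c(body,
              svg_line(ml, ys(p), w - mr, ys(p), "lane", "#999999", 1),
              svg_text(ml - 8, ys(p) + 4, p))
  }
  for (t in seq_len(n))
    body <- c(body, svg_text(xs(t), h - 8, t, class = "tick",
                             anchor = "middle"))
  cols <- if (nrow(recs) > 0L) record_colors(recs, ordering, style)
          else character(0)
  for (r in seq_len(nrow(recs))) {
    x1 <- xs(recs$t_source[r]); y1 <- ys(recs$source[r])
    x2 <- xs(recs$t_target[r]); y2 <- ys(recs$target[r])
    if (abs(x2 - x1) < 1e-9) {           # lag-0: bulge sideways
      cx <- x1 + 36; cy <- (y1 + y2) / 2
    } else {
      cx <- (x1 + x2) / 2
      cy <- (y1 + y2) / 2 - 0.35 * (abs(x2 - x1) + 18)
    }
    body <- c(body, sprintf(
      '<path class="arc" d="M %s %s Q %s %s %s %s" fill="none" stroke="%s" stroke-width="%s" stroke-opacity="%s"/>',
      fmt(x1), fmt(y1), fmt(cx), fmt(cy), fmt(x2), fmt(y2),
      cols[r], fmt(style$base_size * recs$weight[r]),
      fmt(1 - style$transparency)))
  }
  svg_doc(w, h, body)
}

#' Circular view for a single time point
#'
#' Phenotypes are equal segments of a circle (spans sum to 360 degrees);
#' each record at the chosen time point becomes a chord between the
#' midpoints of its endpoint segments, with thickness `base_size * weight`
#' and the same color rule as the linear view.
#'
#' @param connections a [connection_set].
#' @param timepoint 1-based time point (records with `t_source ==
#'   timepoint`; with `style$cumulative`, all up to it).
#' @param style a [style_spec()].
#' @param phenotypes segment set and order (must cover the records'
#'   phenotypes).
#' @return SVG text. Segments carry `data-span` attributes in degrees.
#' @export
render_circular <- function(connections, timepoint, style = style_spec(),
                            phenotypes) {
  stopifnot(inherits(connections, "connection_set"))
  used <- unique(c(connections$source, connections$target))
  if (length(setdiff(used, phenotypes)) > 0L)
    abort_key(sprintf("phenotype '%s' missing from segment list",
                      setdiff(used, phenotypes)[1L]))
  keep <- if (style$cumulative) connections$t_source <= timepoint
          else connections$t_source == timepoint
  recs <- connections[keep, , drop = FALSE]
  P <- length(phenotypes)
  w <- 520; h <- 520; cx0 <- w / 2; cy0 <- h / 2
  r_out <- 210; r_in <- 190
  span <- 360 / P
  pal <- arc_palette(style$palette, P, style$single_color)
  deg2rad <- pi / 180
  pt <- function(r, a) c(cx0 + r * cos(a * deg2rad),
                         cy0 - r * sin(a * deg2rad))
  body <- character(0)
  for (i in seq_len(P)) {
    a0 <- (i - 1) * span; a1 <- i * span
    p0 <- pt(r_out, a0); p1 <- pt(r_out, a1)
    q1 <- pt(r_in, a1); q0 <- pt(r_in, a0)
    large <- if (span > 180) 1 else 0
    body <- c(body, sprintf(
      '<path class="segment" data-phenotype="%s" data-span="%.8f" d="M %s %s A %s %s 0 %d 0 %s %s L %s %s A %s %s 0 %d 1 %s %s Z" fill="%s"/>',
      phenotypes[i], span,
      fmt(p0[1]), fmt(p0[2]), fmt(r_out), fmt(r_out), large,
      fmt(p1[1]), fmt(p1[2]), fmt(q1[1]), fmt(q1[2]),
      fmt(r_in), fmt(r_in), large, fmt(q0[1]), fmt(q0[2]), pal[i]))
    mid <- pt(r_out + 16, (a0 + a1) / 2)
    body <- c(body, svg_text(mid[1], mid[2], phenotypes[i],
                             anchor = "middle"))
  }
  cols <- if (nrow(recs) > 0L) record_colors(recs, phenotypes, style)
          else character(0)
  for (r in seq_len(nrow(recs))) {
    am <- (match(recs$source[r], phenotypes) - 0.5) * span
    bm <- (match(recs$target[r], phenotypes) - 0.5) * span
    p1 <- pt(r_in, am); p2 <- pt(r_in, bm)
    body <- c(body, sprintf(
      '<path class="chord" d="M %s %s Q %s %s %s %s" fill="none" stroke="%s" stroke-width="%s" stroke-opacity="%s"/>',
      fmt(p1[1]), fmt(p1[2]), fmt(cx0), fmt(cy0), fmt(p2[1]), fmt(p2[2]),
      cols[r], fmt(style$base_size * recs$weight[r]),
      fmt(1 - style$transparency)))
  }
  svg_doc(w, h, body)
}

project3d <- function(x, y, z, camera) {
  az <- camera[1] * pi / 180; el <- camera[2] * pi / 180
  sx <- x * cos(az) - y * sin(az)
  sy <- (x * sin(az) + y * cos(az)) * sin(el) - z * cos(el)
  cbind(sx, sy)
}

#' 3D-perspective arc view
#'
#' Lanes run along one ground axis, time along the other; each connection is
#' an arc standing on the ground plane whose apex height is
#' `unit_height * weight` (recorded in the `data-apex` attribute before
#' projection). An optional bar series draws one column per time point,
#' scaled to the series maximum. Output is fully determined by the inputs.
#'
#' @inheritParams render_linear
#' @param barseries optional `bar_series` of length `n_timepoints`.
#' @return SVG text.
#' @export
render_3d <- function(connections, ordering, style = style_spec(),
                      barseries = NULL, timepoint = NULL,
                      n_timepoints = NULL) {
  stopifnot(inherits(connections, "connection_set"))
  used <- unique(c(connections$source, connections$target))
  if (length(setdiff(used, ordering)) > 0L)
    abort_key(sprintf("phenotype '%s' missing from ordering",
                      setdiff(used, ordering)[1L]))
  n <- n_timepoints %||% max(c(connections$t_target, 1L))
  if (!is.null(barseries)) {
    if (length(barseries$values) != n)
      abort_format(sprintf("bar series has %d values but the view has %d time points",
                           length(barseries$values), n))
  }
  recs <- select_records(connections, timepoint, style$cumulative)
  P <- length(ordering)
  w <- 840; h <- 560
  # model units: time 0..(n-1) on x, lane 0..(P-1) on y, height on z with
  # one weight unit == zscale model units (max arc reaches z = 6)
  zscale <- 6 / max(c(recs$weight, 1))
  lat <- expand.grid(x = c(0, n - 1), y = c(0, P - 1), z = c(0, 6))
  proj <- project3d(lat$x, lat$y, lat$z, style$camera)
  rngx <- range(proj[, 1]); rngy <- range(proj[, 2])
  pad <- 60
  sc <- min((w - 2 * pad) / max(diff(rngx), 1e-9),
            (h - 2 * pad) / max(diff(rngy), 1e-9))
  tocanvas <- function(m) cbind(pad + (m[, 1] - rngx[1]) * sc,
                                h - pad - (m[, 2] - rngy[1]) * sc)
  model <- function(t, lane_idx, z_weight)
    tocanvas(project3d(t - 1, lane_idx - 1, z_weight * zscale, style$camera))
  body <- character(0)
  for (i in seq_len(P)) {
    seg <- model(c(1, n), c(i, i), c(0, 0))
    body <- c(body,
              svg_line(seg[1, 1], seg[1, 2], seg[2, 1], seg[2, 2],
                       "lane", "#999999", 1),
              svg_text(seg[1, 1] - 8, seg[1, 2] + 4, ordering[i]))
  }
  for (t in seq_len(n)) {
    seg <- model(c(t, t), c(1, P), c(0, 0))
    body <- c(body, svg_line(seg[1, 1], seg[1, 2], seg[2, 1], seg[2, 2],
                             "grid", "#DDDDDD", 0.5))
  }
  if (!is.null(barseries)) {
    vmax <- max(barseries$values)
    for (t in seq_len(n)) {
      hgt <- if (vmax > 0) barseries$values[t] / vmax * 4 else 0
      seg <- model(c(t, t), c(0, 0), c(0, hgt))
      body <- c(body, sprintf(
        '<line class="bar" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#888888" stroke-width="6" data-value="%s"/>',
        fmt(seg[1, 1]), fmt(seg[1, 2]), fmt(seg[2, 1]), fmt(seg[2, 2]),
        fmt(barseries$values[t])))
    }
  }
  cols <- if (nrow(recs) > 0L) record_colors(recs, ordering, style)
          else character(0)
  for (r in seq_len(nrow(recs))) {
    t1 <- recs$t_source[r]; t2 <- recs$t_target[r]
    l1 <- match(recs$source[r], ordering); l2 <- match(recs$target[r], ordering)
    apex <- style$unit_height * recs$weight[r]
    s <- seq(0, 1, length.out = 21)
    pts <- model(t1 + s * (t2 - t1), l1 + s * (l2 - l1),
                 recs$weight[r] * 4 * s * (1 - s))
    body <- c(body, sprintf(
      '<polyline class="arc" data-apex="%s" points="%s" fill="none" stroke="%s" stroke-width="1.5" stroke-opacity="%s"/>',
      fmt(apex),
      paste(sprintf("%s,%s", fmt(pts[, 1]), fmt(pts[, 2])), collapse = " "),
      cols[r], fmt(1 - style$transparency)))
  }
  svg_doc(w, h, body)
}

#' Heat map of gene-associated values at one time point
#'
#' Rows (genes) and columns (phenotypes) follow the supplied clustering
#' orders; cells map linearly onto a diverging blue-white-red ramp over the
#' observed value range (a constant matrix maps entirely to the midpoint
#' color); missing cells are grey.
#'
#' @param dataset a [pheno_dataset].
#' @param timepoint 1-based time point.
#' @param cluster_result optional list with `row_order`, `col_order` (from
#'   [cluster_heatmap()]); default keeps input order.
#' @param style a [style_spec()].
#' @return SVG text; one `rect.cell` per gene x phenotype cell.
#' @export
render_heatmap <- function(dataset, timepoint, cluster_result = NULL,
                           style = style_spec()) {
  stopifnot(inherits(dataset, "pheno_dataset"))
  if (timepoint < 1L || timepoint > dataset$n_timepoints)
    abort_value("time point out of range")
  m <- matrix(dataset$values[, , timepoint], nrow = length(dataset$genes),
              dimnames = list(dataset$genes, dataset$phenotypes))
  ro <- cluster_result$row_order %||% seq_len(nrow(m))
  co <- cluster_result$col_order %||% seq_len(ncol(m))
  m <- m[ro, co, drop = FALSE]
  ramp <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  rng <- range(m, na.rm = TRUE)
  cell_col <- function(v) {
    if (is.na(v)) return("#CCCCCC")
    if (!is.finite(rng[1]) || diff(rng) < .Machine$double.eps)
      return(ramp[51])
    ramp[1 + round((v - rng[1]) / diff(rng) * 100)]
  }
  cw <- 22; ch <- 14; ml <- 90; mt <- 40
  w <- ml + cw * ncol(m) + 20; h <- mt + ch * nrow(m) + 20
  body <- character(0)
  for (j in seq_len(ncol(m)))
    body <- c(body, svg_text(ml + (j - 0.5) * cw, mt - 8, colnames(m)[j],
                             anchor = "middle"))
  for (i in seq_len(nrow(m))) {
    body <- c(body, svg_text(ml - 6, mt + (i - 0.5) * ch + 4,
                             rownames(m)[i]))
    for (j in seq_len(ncol(m))) {
      body <- c(body, sprintf(
        '<rect class="cell" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        fmt(ml + (j - 1) * cw), fmt(mt + (i - 1) * ch),
        fmt(cw), fmt(ch), cell_col(m[i, j])))
    }
  }
  svg_doc(w, h, body)
}

#' Line plot of one phenotype's values over time
#'
#' One polyline per gene over time points 1..n; a missing value breaks the
#' polyline into separate segments.
#'
#' @param dataset a [pheno_dataset].
#' @param phenotype phenotype label.
#' @param style a [style_spec()].
#' @return SVG text; polyline elements carry class `series`.
#' @export
render_lineplot <- function(dataset, phenotype, style = style_spec()) {
  stopifnot(inherits(dataset, "pheno_dataset"))
  if (!phenotype %in% dataset$phenotypes)
    abort_key(sprintf("unknown phenotype '%s'", phenotype))
  n <- dataset$n_timepoints
  vals <- matrix(dataset$values[, phenotype, ], nrow = length(dataset$genes))
  rng <- range(vals, na.rm = TRUE)
  if (!is.finite(rng[1])) rng <- c(0, 1)
  if (diff(rng) < .Machine$double.eps) rng <- rng + c(-0.5, 0.5)
  w <- 640; h <- 360; ml <- 50; mr <- 20; mt <- 24; mb <- 32
  xs <- function(t) if (n == 1L) ml + (w - ml - mr) / 2 else
    ml + (t - 1) / (n - 1) * (w - ml - mr)
  ys <- function(v) mt + (rng[2] - v) / diff(rng) * (h - mt - mb)
  body <- c(svg_line(ml, h - mb, w - mr, h - mb, "axis", "#333333", 1),
            svg_line(ml, mt, ml, h - mb, "axis", "#333333", 1),
            svg_text(w / 2, 14, phenotype, anchor = "middle"))
  pal <- arc_palette(if (identical(style$palette, "single")) "single"
                     else style$palette,
                     min(length(dataset$genes),
                         if (identical(style$palette, "single")) length(dataset$genes) else 8L),
                     style$single_color)
  for (i in seq_along(dataset$genes)) {
    v <- vals[i, ]
    runs <- split(seq_len(n), cumsum(is.na(v))[seq_len(n)])
    col <- pal[(i - 1L) %% length(pal) + 1L]
    for (run in runs) {
      run <- run[!is.na(v[run])]
      if (length(run) == 0L) next
      body <- c(body, sprintf(
        '<polyline class="series" data-gene="%s" points="%s" fill="none" stroke="%s" stroke-width="1.2"/>',
        dataset$genes[i],
        paste(sprintf("%s,%s", fmt(xs(run)), fmt(ys(v[run]))),
              collapse = " "), col))
    }
  }
  for (t in seq_len(n))
    body <- c(body, svg_text(xs(t), h - 10, t, class = "tick",
                             anchor = "middle"))
  svg_doc(w, h, body)
}

#' Write SVG text to a file
#'
#' @param svg character scalar from a `render_*` function.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
render_save <- function(svg, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(svg, con, eos = NULL)
  invisible(path)
}

#' Count drawable connection elements in an SVG
#'
#' Utility for audits: the number of `class="arc"` / `class="chord"`
#' elements, which equals the number of rendered connection records.
#'
#' @param svg SVG text.
#' @return integer count.
#' @export
count_arc_elements <- function(svg) {
  sum(lengths(regmatches(svg, gregexpr('class="(arc|chord)"', svg))))
}
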