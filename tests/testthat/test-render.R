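demo_connections <- function() {
  connection_set(
    source = c("A", "B", "A", "C"), target = c("B", "C", "C", "A"),
    t_source = c(1L, 2L, 2L, 3L), t_target = c(2L, 3L, 3L, 3L),
    genes = list(c("g1", "g2"), "g3", c("g1", "g3", "g4"), "g2"),
    directed = c(TRUE, TRUE, TRUE, FALSE))
}

test_that("renderers are pure: identical inputs give byte-identical SVG", {
  cs <- demo_connections()
  ordering <- c("A", "B", "C")
  st <- style_spec()
  expect_identical(render_linear(cs, ordering, st, n_timepoints = 3),
                   render_linear(cs, ordering, st, n_timepoints = 3))
  expect_identical(render_circular(cs, 2, st, ordering),
                   render_circular(cs, 2, st, ordering))
  expect_identical(render_3d(cs, ordering, st, n_timepoints = 3),
                   render_3d(cs, ordering, st, n_timepoints = 3))
})

test_that("stroke width and apex height are proportional to weight", {
  genes <- lapply(1:5, function(w) sprintf("g%d_%d", w, seq_len(w)))
  cs <- connection_set(rep("A", 5), rep("B", 5), rep(1L, 5), rep(2L, 5),
                       genes, rep(TRUE, 5))
  svg <- render_linear(cs, c("A", "B"), style_spec(base_size = 2),
                       n_timepoints = 2)
  widths <- as.numeric(sub('.*stroke-width="([0-9.]+)".*', "\\1",
                           grep('class="arc"', strsplit(svg, "\n")[[1]],
                                value = TRUE)))
  expect_equal(widths / widths[1], 1:5)
  svg3 <- render_3d(cs, c("A", "B"), style_spec(unit_height = 10),
                    n_timepoints = 2)
  apexes <- as.numeric(sub('.*data-apex="([0-9.]+)".*', "\\1",
                           grep('class="arc"', strsplit(svg3, "\n")[[1]],
                                value = TRUE)))
  expect_equal(apexes / apexes[1], 1:5)
  expect_equal(apexes, 10 * (1:5))
})

test_that("every connection record yields exactly one drawable element", {
  cs <- demo_connections()
  svg <- render_linear(cs, c("A", "B", "C"), n_timepoints = 3)
  expect_equal(count_arc_elements(svg), nrow(cs))
  empty <- render_linear(connection_set(), c("A", "B"), n_timepoints = 3)
  expect_equal(count_arc_elements(empty), 0L)
  expect_match(empty, 'class="lane"')
  # timepoint selection: only records at (vs up to) the time point
  one <- render_linear(cs, c("A", "B", "C"), style_spec(),
                       timepoint = 3, n_timepoints = 3)
  expect_equal(count_arc_elements(one), 3L)
  cum <- render_linear(cs, c("A", "B", "C"), style_spec(cumulative = TRUE),
                       timepoint = 3, n_timepoints = 3)
  expect_equal(count_arc_elements(cum), 4L)
})

test_that("directed arcs carry the target phenotype's palette color", {
  cs <- connection_set("A", "B", 1L, 2L, list("g1"), TRUE)
  ordering <- c("A", "B")
  pal <- arc_palette("Set2", 2)
  svg <- render_linear(cs, ordering, n_timepoints = 2)
  arc <- grep('class="arc"', strsplit(svg, "\n")[[1]], value = TRUE)
  expect_match(arc, pal[2], fixed = TRUE)
  # undirected records use the single connection color
  csu <- connection_set("A", "B", 1L, 1L, list("g1"), FALSE)
  svgu <- render_linear(csu, ordering, n_timepoints = 2)
  arcu <- grep('class="arc"', strsplit(svgu, "\n")[[1]], value = TRUE)
  expect_match(arcu, "#555555", fixed = TRUE)
  expect_error(render_linear(cs, "A", n_timepoints = 2),
               class = "phenoarc_key_error")
})

test_that("circular segments are equal and close to 360 degrees", {
  cs <- demo_connections()
  for (P in c(3, 4, 7)) {
    phen <- c("A", "B", "C", LETTERS[4:7])[1:P]
    svg <- render_circular(filter_connections(cs, phenotype_subset = phen),
                           2, style_spec(), phen)
    spans <- as.numeric(sub('.*data-span="([0-9.]+)".*', "\\1",
                            grep('class="segment"', strsplit(svg, "\n")[[1]],
                                 value = TRUE)))
    expect_equal(length(spans), P)
    expect_true(all(abs(spans - 360 / P) < 1e-6))
    expect_lt(abs(sum(spans) - 360), 1e-6)
  }
  # no records at t: segments only
  none <- render_circular(connection_set(), 1, style_spec(), c("A", "B"))
  expect_equal(count_arc_elements(none), 0L)
  expect_equal(length(grep("segment", strsplit(none, "\n")[[1]])), 2L)
})

test_that("3d view renders bar series and tolerates degenerate ones", {
  cs <- demo_connections()
  bars <- parse_barseries("1 4 2", 3)
  svg <- render_3d(cs, c("A", "B", "C"), barseries = bars, n_timepoints = 3)
  expect_equal(length(grep('class="bar"', strsplit(svg, "\n")[[1]])), 3L)
  zero <- parse_barseries("0 0 0", 3)
  expect_no_error(render_3d(cs, c("A", "B", "C"), barseries = zero,
                            n_timepoints = 3))
  expect_error(render_3d(cs, c("A", "B", "C"),
                         barseries = parse_barseries("1 2", 2),
                         n_timepoints = 3),
               class = "phenoarc_format_error")
})

test_that("heat map draws one cell per gene x phenotype", {
  d <- parse_dataset("g1 A 1 2\ng1 B 3 4\ng2 A 5 6\ng2 B 7 8")
  svg <- render_heatmap(d, 1)
  expect_equal(length(grep('class="cell"', strsplit(svg, "\n")[[1]])), 4L)
  # constant matrix maps to the midpoint color everywhere
  dc <- parse_dataset("g1 A 1 1\ng1 B 1 1\ng2 A 1 1\ng2 B 1 1")
  svgc <- render_heatmap(dc, 1)
  cells <- grep('class="cell"', strsplit(svgc, "\n")[[1]], value = TRUE)
  fills <- unique(sub('.*fill="([^"]+)".*', "\\1", cells))
  expect_equal(length(fills), 1L)
  # clustering orders are honored
  cl <- cluster_heatmap(matrix(d$values[, , 1], 2,
                               dimnames = list(d$genes, d$phenotypes)))
  expect_no_error(render_heatmap(d, 1, cl))
})

test_that("line plot breaks polylines at missing values", {
  d <- parse_dataset("g1 A 1 NA 3 4")
  svg <- render_lineplot(d, "A")
  expect_equal(length(grep('class="series"', strsplit(svg, "\n")[[1]])), 2L)
  expect_error(render_lineplot(d, "Z"), class = "phenoarc_key_error")
})

test_that("palettes give distinct qualitative or uniform single colors", {
  expect_equal(length(unique(arc_palette("Set2", 7))), 7L)
  expect_equal(length(unique(arc_palette("single", 7))), 1L)
  expect_equal(length(arc_palette("single", 7)), 7L)
  expect_error(arc_palette("Set2", 0), class = "phenoarc_value_error")
  expect_error(arc_palette("Dark2", 9), "single",
               class = "phenoarc_value_error")
  # style validation
  expect_error(style_spec(transparency = 1.2), class = "phenoarc_value_error")
  expect_error(style_spec(base_size = 0), class = "phenoarc_value_error")
})
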