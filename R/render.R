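#' @title Deterministic SVG rendering
#'
#' @description
#' Renders one tree (view mode) or two trees side-by-side (compare mode)
#' as SVG 1.1 text. Rendering is a pure function of its inputs: repeated
#' calls are byte-identical. Visible leaves and collapsed stubs occupy
#' evenly spaced rows; collapsed subtrees are triangles sized by their
#' leaf count; in compare mode every visible node carries a colour-bin
#' class (`bin-0` ... bluest bin) derived from its BCN score, the second
#' tree is mirrored with labels facing inward, and highlight / selection
#' / search-path overlays use dedicated CSS classes.
#'
#' @name render
NULL

#' Rendering parameters
#'
#' @param viewport drawing area `c(width_px, height_px)` per tree panel
#' @param label_height pixels per leaf row (also the font size)
#' @param scheme ordered colour ramp from low similarity (yellow) to high
#'   (blue); the default is the 9-class ColorBrewer YlGnBu sequential
#'   ramp. Must have at least 3 entries; its length defines the number
#'   of score bins (uniform on `[0, 1]`).
#' @param highlight_color,selection_color overlay colours (green / red)
#' @param x_mode `"cladogram"` (x proportional to depth) or
#'   `"phylogram"` (x proportional to cumulative branch length; absent
#'   lengths count as 0)
#' @return a `render_spec`
#' @export
render_spec <- function(viewport = c(960, 600), label_height = 16,
                        scheme = c("#ffffd9", "#edf8b1", "#c7e9b4",
                                   "#7fcdbb", "#41b6c4", "#1d91c0",
                                   "#225ea8", "#253494", "#081d58"),
                        highlight_color = "#2ca02c",
                        selection_color = "#d62728",
                        x_mode = c("cladogram", "phylogram")) {
  stopifnot(length(viewport) == 2L, all(viewport > 0), label_height > 0)
  if (length(scheme) < 3L) {
    tree_error("colour scheme needs at least 3 bins", "render_spec_error")
  }
  structure(list(viewport = as.numeric(viewport),
                 label_height = as.numeric(label_height),
                 scheme = as.character(scheme),
                 color_bins = length(scheme),
                 highlight_color = highlight_color,
                 selection_color = selection_color,
                 x_mode = match.arg(x_mode)),
            class = "render_spec")
}

#' Map a similarity score to a colour bin
#'
#' @param score numeric score(s) in `[0, 1]`
#' @param spec a [render_spec()]
#' @return integer bin index in `[0, color_bins - 1]`, computed as
#'   `floor(score * color_bins)` clamped at the top bin; monotone
#'   non-decreasing in `score`
#' @export
color_bin <- function(score, spec) {
  if (any(is.na(score)) || any(score < 0) || any(score > 1)) {
    tree_error("scores must lie in [0, 1]", "score_range_error")
  }
  pmin(as.integer(floor(score * spec$color_bins)), spec$color_bins - 1L)
}

#' Rectangular tree layout
#'
#' Assigns pixel coordinates to every visible node: leaves and collapsed
#' stubs get evenly spaced rows top to bottom in drawing order, internal
#' nodes sit at the mean y of their visible children, and x grows with
#' depth (cladogram) or cumulative branch length (phylogram). Traversal
#' never descends below a collapsed node. With `mirror = TRUE` the x axis
#' is reflected for the right-hand tree of a pair.
#'
#' @param tree a [ctree]
#' @param state a [viz_state()]
#' @param spec a [render_spec()]
#' @param mirror reflect x coordinates
#' @return data frame with `node`, `x`, `y`, `tip` (occupies a row),
#'   `stub` (collapsed triangle), in drawing order
#' @export
layout_rect <- function(tree, state, spec, mirror = FALSE) {
  vis <- visible_nodes(tree, state)
  coll <- logical(n_nodes(tree))
  coll[state$collapsed] <- TRUE
  tip <- tree$is_leaf[vis] | coll[vis]
  n_rows <- sum(tip)
  h <- spec$viewport[2]
  w_tree <- spec$viewport[1] * 0.72   # remainder is label space
  row_h <- h / max(1L, n_rows)

  y <- rep(NA_real_, n_nodes(tree))
  y[vis[tip]] <- (seq_len(n_rows) - 0.5) * row_h
  for (v in rev(vis)) {
    if (is.na(y[v])) y[v] <- mean(y[tree$children[[v]]])
  }

  if (spec$x_mode == "cladogram") {
    xdep <- as.numeric(tree$depth)
  } else {
    xdep <- numeric(n_nodes(tree))
    for (v in tree$preorder) {
      p <- tree$parent[v]
      el <- tree$edge_len[v]
      xdep[v] <- (if (p == 0L) 0 else xdep[p]) + (if (is.na(el)) 0 else el)
    }
  }
  xmax <- max(xdep[vis], 1e-9)
  x <- xdep / xmax * w_tree
  if (mirror) x <- spec$viewport[1] - x

  data.frame(node = vis, x = x[vis], y = y[vis], tip = tip,
             stub = coll[vis] & !tree$is_leaf[vis])
}

fmt_px <- function(x) sprintf("%.2f", x)

svg_style <- function(spec) {
  bins <- paste(vapply(seq_len(spec$color_bins) - 1L, function(b) {
    sprintf(".bin-%d{fill:%s;}", b, spec$scheme[b + 1L])
  }, character(1)), collapse = "")
  paste0("<style>",
         ".edge{stroke:#555555;stroke-width:1;fill:none;}",
         ".search-path{stroke:#ff8c00;stroke-width:2.5;}",
         sprintf(".highlight{stroke:%s;stroke-width:2;}", spec$highlight_color),
         sprintf("circle.highlight{fill:%s;stroke:none;}", spec$highlight_color),
         sprintf(".selected{fill:%s;stroke:none;}", spec$selection_color),
         ".collapsed{fill:#b8b8d0;stroke:#555555;stroke-width:0.5;}",
         sprintf(".leaf{font-family:monospace;font-size:%spx;}",
                 fmt_px(spec$label_height * 0.75)),
         bins,
         "</style>")
}

# Emit SVG fragments for one laid-out tree panel.
render_panel <- function(tree, state, spec, lay, scores = NULL,
                         mirror = FALSE, offset_x = 0) {
  coords_x <- stats::setNames(lay$x + offset_x, lay$node)
  coords_y <- stats::setNames(lay$y, lay$node)
  hl <- logical(n_nodes(tree))
  for (v in state$highlighted) hl[subtree_nodes(tree, v)] <- TRUE
  sp <- logical(n_nodes(tree))
  sp[state$search_path] <- TRUE
  out <- character(0)
  xs <- function(v) fmt_px(coords_x[[as.character(v)]])
  ys <- function(v) fmt_px(coords_y[[as.character(v)]])
  for (k in seq_len(nrow(lay))) {
    v <- lay$node[k]
    p <- tree$parent[v]
    if (p != 0L) {
      cls <- "edge"
      if (hl[v]) cls <- paste(cls, "highlight")
      if (sp[p] && sp[v]) cls <- paste(cls, "search-path")
      out <- c(out, sprintf('<path class="%s" d="M%s,%s V%s H%s"/>',
                            cls, xs(p), ys(p), ys(v), xs(v)))
    }
  }
  row_h <- spec$viewport[2] / max(1L, sum(lay$tip))
  for (k in which(lay$stub)) {
    v <- lay$node[k]
    frac <- min(0.15, tree$clade_size[v] / tree$n_leaves * 0.15 + 0.03)
    w <- spec$viewport[1] * 0.72 * frac * (if (mirror) -1 else 1)
    cls <- if (hl[v]) "collapsed highlight" else "collapsed"
    out <- c(out, sprintf('<polygon class="%s" points="%s,%s %s,%s %s,%s"/>',
      cls, xs(v), ys(v),
      fmt_px(coords_x[[as.character(v)]] + w), fmt_px(coords_y[[as.character(v)]] - row_h * 0.45),
      fmt_px(coords_x[[as.character(v)]] + w), fmt_px(coords_y[[as.character(v)]] + row_h * 0.45)))
  }
  if (!is.null(scores)) {
    for (k in seq_len(nrow(lay))) {
      v <- lay$node[k]
      cls <- sprintf("node bin-%d", color_bin(scores[v], spec))
      out <- c(out, sprintf('<circle class="%s" cx="%s" cy="%s" r="3"/>',
                            cls, xs(v), ys(v)))
    }
  }
  for (k in which(lay$tip & tree$is_leaf[lay$node])) {
    v <- lay$node[k]
    lab <- tree$label[v]
    cls <- if (hl[v]) "leaf highlight" else "leaf"
    anchor <- if (mirror) ' text-anchor="end"' else ""
    dx <- if (mirror) -4 else 4
    out <- c(out, sprintf('<text class="%s"%s x="%s" y="%s">%s</text>',
                          cls, anchor,
                          fmt_px(coords_x[[as.character(v)]] + dx),
                          fmt_px(coords_y[[as.character(v)]] + spec$label_height * 0.25),
                          xml_escape(lab)))
  }
  sel <- state$selected
  if (length(sel) == 1L && !is.na(sel) && sel %in% lay$node) {
    out <- c(out, sprintf('<circle class="selected" cx="%s" cy="%s" r="5"/>',
                          xs(sel), ys(sel)))
  }
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_open <- function(w, h) {
  sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                 'width="%s" height="%s" viewBox="0 0 %s %s">'),
          fmt_px(w), fmt_px(h), fmt_px(w), fmt_px(h))
}

#' Render a single tree (view mode)
#'
#' @param tree a [ctree]
#' @param state a [viz_state()]; its `search_path` and `selected` fields
#'   drive the overlays
#' @param spec a [render_spec()]
#' @return SVG text (one `<text>` element per visible leaf, one triangle
#'   per collapsed node); byte-identical across repeated calls
#' @export
render_view <- function(tree, state = viz_state(), spec = render_spec()) {
  lay <- layout_rect(tree, state, spec)
  paste(c(svg_open(spec$viewport[1], spec$viewport[2]),
          svg_style(spec),
          '<g class="tree">',
          render_panel(tree, state, spec, lay),
          "</g></svg>"),
        collapse = "\n")
}

#' Render two trees side-by-side (compare mode)
#'
#' Lays the first tree out on the left and the second mirrored on the
#' right (labels facing inward). Every visible node is drawn as a circle
#' whose colour bin encodes its BCN score against the opposing tree.
#' Scores are obtained lazily: only the visible nodes' scores are
#' computed (or filled into a partially computed `cmp`), honouring the
#' just-before-rendering contract.
#'
#' @param t1,t2 trees on the same leaf label set
#' @param cmp optional `tree_comparison`; missing visible-node scores are
#'   computed on demand, `NULL` computes exactly the visible nodes
#' @param s1,s2 the two [viz_state()]s
#' @param spec a [render_spec()]
#' @return SVG text; the comparison actually used (with its `n_computed`
#'   counter) is attached as attribute `"comparison"`
#' @export
render_compare <- function(t1, t2, cmp = NULL, s1 = viz_state(),
                           s2 = viz_state(), spec = render_spec()) {
  vis1 <- visible_nodes(t1, s1)
  vis2 <- visible_nodes(t2, s2)
  if (is.null(cmp)) {
    cmp <- compare_trees(t1, t2, method = "fast",
                         restrict1 = vis1, restrict2 = vis2)
  } else {
    cmp <- compare_update(cmp, t1, t2, nodes1 = vis1, nodes2 = vis2)
  }
  gap <- 40
  lay1 <- layout_rect(t1, s1, spec)
  lay2 <- layout_rect(t2, s2, spec, mirror = TRUE)
  total_w <- 2 * spec$viewport[1] + gap
  svg <- paste(c(svg_open(total_w, spec$viewport[2]),
                 svg_style(spec),
                 '<g class="tree-left">',
                 render_panel(t1, s1, spec, lay1, scores = cmp$score1),
                 "</g>",
                 '<g class="tree-right">',
                 render_panel(t2, s2, spec, lay2, scores = cmp$score2,
                              mirror = TRUE, offset_x = spec$viewport[1] + gap),
                 "</g></svg>"),
               collapse = "\n")
  attr(svg, "comparison") <- cmp
  svg
}
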