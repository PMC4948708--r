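#' @title Newick and extended-Newick input/output
#'
#' @description
#' Reads and writes trees in standard (Felsenstein) Newick. An extended
#' dialect carries visualization state and comparison annotations as
#' NHX-style bracketed tags (`[&&NHX:collapsed=1:highlighted=1:S=0.5]`)
#' attached after the branch length; because all annotations live inside
#' comment brackets, plain Newick parsers skip them and still recover the
#' same topology. Internal node labels that look numeric are interpreted
#' as support values. Single-quoted labels use doubled-quote escaping;
#' unquoted labels may not contain structural characters.
#'
#' @name newick
NULL

#' Parse a Newick string into a tree
#'
#' @param text a single Newick string terminated by `";"`; may carry
#'   NHX-style extended annotations (see [newick])
#' @return a [ctree]; if the text carried state annotations the result has
#'   a `$state` [viz_state()] and per-node `$node_score` values
#' @details Malformed input raises a condition of class
#'   `newick_parse_error` carrying the 1-based character `offset`;
#'   duplicate leaf labels raise `duplicate_label_error` naming the labels.
#'   Branch lengths absent in the text are recorded as `NA`, never zero.
#'   Polytomies and singleton (one-child) internal nodes are accepted.
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2),(C,D));")
#' leaf_labels(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    tree_error("input must be a single non-empty Newick string",
               "newick_parse_error", offset = 1L)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  nchr <- length(chars)
  pos <- 1L

  parent <- integer(0)
  children <- list()
  label <- character(0)
  elen <- numeric(0)
  supp <- numeric(0)
  coll <- logical(0)
  high <- logical(0)
  score <- numeric(0)
  meta <- new.env(parent = emptyenv())  # viewport tags, seen-extended flag
  meta$vw <- NA_real_; meta$vh <- NA_real_; meta$lh <- NA_real_
  meta$extended <- FALSE

  perr <- function(msg, at = pos) {
    tree_error(sprintf("newick parse error at character %d: %s", at, msg),
               "newick_parse_error", offset = at)
  }
  peek <- function() if (pos <= nchr) chars[pos] else ""
  skip_ws <- function() {
    while (pos <= nchr && chars[pos] %in% c(" ", "\t", "\n", "\r")) pos <<- pos + 1L
  }
  new_node <- function(par) {
    parent <<- c(parent, par)
    children[[length(parent)]] <<- integer(0)
    label <<- c(label, NA_character_)
    elen <<- c(elen, NA_real_)
    supp <<- c(supp, NA_real_)
    coll <<- c(coll, FALSE)
    high <<- c(high, FALSE)
    score <<- c(score, NA_real_)
    length(parent)
  }
  structural <- c("(", ")", ",", ":", ";", "[", "]", "'")
  parse_label <- function() {
    if (peek() == "'") {
      start <- pos
      pos <<- pos + 1L
      out <- character(0)
      repeat {
        if (pos > nchr) perr("unterminated quoted label", start)
        c0 <- chars[pos]
        if (c0 == "'") {
          if (pos + 1L <= nchr && chars[pos + 1L] == "'") {
            out <- c(out, "'"); pos <<- pos + 2L
          } else { pos <<- pos + 1L; break }
        } else { out <- c(out, c0); pos <<- pos + 1L }
      }
      paste(out, collapse = "")
    } else {
      out <- character(0)
      while (pos <= nchr && !(chars[pos] %in% structural) &&
             !(chars[pos] %in% c(" ", "\t", "\n", "\r"))) {
        out <- c(out, chars[pos]); pos <<- pos + 1L
      }
      paste(out, collapse = "")
    }
  }
  parse_length <- function() {
    start <- pos
    out <- character(0)
    while (pos <= nchr && grepl("[0-9eE.+-]", chars[pos])) {
      out <- c(out, chars[pos]); pos <<- pos + 1L
    }
    val <- suppressWarnings(as.numeric(paste(out, collapse = "")))
    if (!length(out) || is.na(val)) perr("expected a branch length", start)
    val
  }
  parse_comments <- function(id) {
    while (peek() == "[") {
      start <- pos
      pos <<- pos + 1L
      out <- character(0)
      while (pos <= nchr && chars[pos] != "]") {
        out <- c(out, chars[pos]); pos <<- pos + 1L
      }
      if (pos > nchr) perr("unterminated comment", start)
      pos <<- pos + 1L
      body <- paste(out, collapse = "")
      if (startsWith(body, "&&NHX")) {
        meta$extended <- TRUE
        tags <- strsplit(sub("^&&NHX:?", "", body), ":", fixed = TRUE)[[1]]
        for (tg in tags[nzchar(tags)]) {
          kv <- strsplit(tg, "=", fixed = TRUE)[[1]]
          if (length(kv) != 2L) next
          switch(kv[1],
            collapsed   = { coll[id] <<- kv[2] == "1" },
            highlighted = { high[id] <<- kv[2] == "1" },
            S           = { score[id] <<- suppressWarnings(as.numeric(kv[2])) },
            vw          = { meta$vw <- suppressWarnings(as.numeric(kv[2])) },
            vh          = { meta$vh <- suppressWarnings(as.numeric(kv[2])) },
            lh          = { meta$lh <- suppressWarnings(as.numeric(kv[2])) })
        }
      }
      skip_ws()
    }
  }
  parse_clade <- function(par) {
    skip_ws()
    id <- new_node(par)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        child <- parse_clade(id)
        children[[id]] <<- c(children[[id]], child)
        skip_ws()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        perr("expected ',' or ')'")
      }
      skip_ws()
      if (!(peek() %in% c(":", ",", ")", ";", "[", ""))) {
        lab <- parse_label()
        if (nzchar(lab)) {
          if (label_is_numeric(lab)) supp[id] <<- as.numeric(lab)
          else label[id] <<- lab
        }
      }
    } else {
      lab <- parse_label()
      if (!nzchar(lab)) perr("expected a leaf label")
      label[id] <<- lab
    }
    skip_ws()
    if (peek() == ":") {
      pos <<- pos + 1L
      skip_ws()
      elen[id] <<- parse_length()
    }
    skip_ws()
    parse_comments(id)
    id
  }

  skip_ws()
  root <- parse_clade(0L)
  skip_ws()
  if (peek() != ";") perr("expected ';' at end of tree")
  pos <- pos + 1L
  skip_ws()
  if (pos <= nchr) perr("unexpected trailing characters")

  state <- NULL
  if (meta$extended) {
    vp <- c(if (is.na(meta$vw)) 960 else meta$vw,
            if (is.na(meta$vh)) 600 else meta$vh)
    state <- viz_state(collapsed = which(coll), highlighted = which(high),
                       viewport = vp,
                       label_height = if (is.na(meta$lh)) 16 else meta$lh)
  }
  seal_tree(parent, children, label, elen, supp,
            state = state,
            node_score = if (any(!is.na(score))) score else NULL)
}

quote_label <- function(lab) {
  if (grepl("[][ \t\n\r():;,']", lab) || !nzchar(lab)) {
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  } else lab
}

#' Write a tree as (extended) Newick
#'
#' @param tree a [ctree]
#' @param include_state emit the extended dialect: NHX-style tags carrying
#'   per-node collapsed/highlighted flags, per-node similarity scores
#'   (`S=`), and the viewport geometry on the root. With `FALSE` the
#'   output is plain Newick that any standard parser reads.
#' @return a Newick string terminated by `";"`. Branch lengths are printed
#'   with 10 significant digits; `parse_newick(write_newick(t, TRUE))`
#'   reproduces topology, labels, lengths, support, and state exactly.
#' @export
write_newick <- function(tree, include_state = FALSE) {
  stopifnot(inherits(tree, "ctree"))
  st <- tree$state
  coll <- high <- logical(n_nodes(tree))
  if (!is.null(st) && include_state) {
    coll[st$collapsed] <- TRUE
    high[st$highlighted] <- TRUE
  }
  score <- tree$node_score
  emit <- function(v) {
    ch <- tree$children[[v]]
    s <- if (length(ch)) {
      inner <- paste(vapply(ch, emit, character(1)), collapse = ",")
      lab <- if (!is.na(tree$label[v])) quote_label(tree$label[v])
             else if (!is.na(tree$support[v])) fmt_num(tree$support[v])
             else ""
      paste0("(", inner, ")", lab)
    } else {
      quote_label(tree$label[v])
    }
    if (!is.na(tree$edge_len[v])) s <- paste0(s, ":", fmt_num(tree$edge_len[v]))
    if (include_state) {
      tags <- character(0)
      if (coll[v]) tags <- c(tags, "collapsed=1")
      if (high[v]) tags <- c(tags, "highlighted=1")
      if (!is.null(score) && !is.na(score[v])) {
        tags <- c(tags, paste0("S=", sprintf("%.6g", score[v])))
      }
      if (v == tree$root && !is.null(st)) {
        tags <- c(tags, paste0("vw=", fmt_num(st$viewport[1])),
                  paste0("vh=", fmt_num(st$viewport[2])),
                  paste0("lh=", fmt_num(st$label_height)))
      }
      if (length(tags)) s <- paste0(s, "[&&NHX:", paste(tags, collapse = ":"), "]")
    }
    s
  }
  paste0(emit(tree$root), ";")
}

#' Read a tree from a Newick file
#' @param path file containing one Newick tree
#' @return a [ctree]
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) {
    tree_error(paste0("cannot read file: ", path), "io_error")
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt)
}

#' Write a tree to a Newick file
#' @param tree a [ctree]
#' @param path output path
#' @param include_state see [write_newick()]
#' @return `path`, invisibly
#' @export
write_newick_file <- function(tree, path, include_state = FALSE) {
  writeLines(write_newick(tree, include_state), path)
  invisible(path)
}
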