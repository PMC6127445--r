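#' Parse a logic-expression file into a Boolean network
#'
#' Reads the `targets, factors` dialect: one rule per line in the form
#' `name, expression`, where the expression uses the operators `&` (AND),
#' `|` (OR), `!` (NOT), parentheses, and the constants `0`/`1`. Lines starting
#' with `#` and blank lines are ignored, as is an optional
#' `targets, factors` header. Names referenced by some expression but carrying
#' no rule of their own become external nodes. Each expression is compiled to
#' a truth table over its referenced variables in first-appearance order.
#'
#' @param path path to the file; exactly one of `path`/`text` must be given.
#' @param text character scalar or vector with the document content (lines).
#' @return a validated [boolean_network()].
#' @examples
#' net <- parse_expression_file(text = c(
#'   "x1, x2 & x3 & !x4",
#'   "x2, x1 & (x2 | x3)",
#'   "x3, x1 | x2"
#' ))
#' external_nodes(net) # x4
#' @export
parse_expression_file <- function(path = NULL, text = NULL) {
  if (is.null(path) == is.null(text))
    stop("supply exactly one of 'path' or 'text'")
  lines <- if (!is.null(path)) readLines(path, warn = FALSE) else
    unlist(strsplit(text, "\n", fixed = TRUE))
  rules <- list()
  order_seen <- character()
  first_rule <- TRUE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (first_rule && grepl("^targets\\s*[,\t]\\s*factors$", ln, ignore.case = TRUE)) {
      first_rule <- FALSE
      next
    }
    first_rule <- FALSE
    sep <- regexpr("[,\t]", ln)
    if (sep < 0)
      stop("line ", i, ": expected 'name, expression'")
    nm <- trimws(substr(ln, 1, sep - 1))
    expr <- trimws(substr(ln, sep + 1, nchar(ln)))
    if (!nzchar(nm)) stop("line ", i, ": empty node name")
    if (!nzchar(expr)) stop("line ", i, ": empty expression")
    if (nm %in% names(rules))
      stop("line ", i, ": duplicate rule for '", nm, "'")
    rules[[nm]] <- compile_expression(expr, line = i)
    order_seen <- c(order_seen, nm, rules[[nm]]$inputs)
  }
  if (length(rules) == 0) stop("document contains no rules")
  nodes <- unique(order_seen)
  boolean_network(rules = rules,
                  external = setdiff(nodes, names(rules)),
                  nodes = nodes)
}

# Compile one logic expression into list(inputs=, table=).
# Tokens are whitelisted before the string is handed to the R parser, so
# evaluation in the sandbox environment below cannot call functions.
compile_expression <- function(expr, line = NA) {
  where <- if (is.na(line)) "" else paste0("line ", line, ": ")
  tok_re <- "[A-Za-z_.][A-Za-z0-9_.]*|[01]|&{1,2}|\\|{1,2}|[!()]|\\s+"
  m <- gregexpr(tok_re, expr)[[1]]
  covered <- sum(attr(m, "match.length"))
  if (m[1] == -1 || covered != nchar(expr))
    stop(where, "syntax error in expression: ", expr)
  toks <- regmatches(expr, gregexpr(tok_re, expr))[[1]]
  toks <- toks[!grepl("^\\s+$", toks)]
  vars <- unique(toks[grepl("^[A-Za-z_.]", toks)])
  k <- length(vars)
  if (k > 24) stop(where, "expression has ", k, " inputs; at most 24 supported")
  parsed <- tryCatch(parse(text = expr)[[1]],
                     error = function(e) stop(where, "syntax error in expression: ",
                                              expr, call. = FALSE))
  asn <- rule_assignments(k)
  env <- new.env(parent = emptyenv())
  for (op in c("&", "&&", "|", "||", "!", "(")) assign(op, get(op, baseenv()), envir = env)
  for (j in seq_len(k)) assign(vars[j], asn[, j], envir = env)
  val <- tryCatch(eval(parsed, env),
                  error = function(e) stop(where, "cannot evaluate expression: ",
                                           conditionMessage(e), call. = FALSE))
  tab <- as.integer(as.logical(val))
  if (length(tab) == 1) tab <- rep(tab, 2^k)
  if (length(tab) != 2^k || anyNA(tab))
    stop(where, "expression did not evaluate to a Boolean function")
  list(inputs = vars, table = tab)
}

#' Read a truth-table directory into a Boolean network
#'
#' Expects one delimited table per regulated node, named `<node>.csv`
#' (comma-delimited; tabs tolerated), whose header lists the input names
#' followed by the node's own name, and whose `2^k` rows enumerate every input
#' assignment exactly once (canonically in ascending binary order with the
#' first input as most significant bit; any row order is accepted as long as
#' the enumeration is complete and duplicate-free). An optional `external.txt`
#' (one name per line) declares input-only nodes, and an optional `nodes.txt`
#' fixes the node order; every input name must resolve to a table or a
#' declared external node.
#'
#' @param path directory to read.
#' @return a validated [boolean_network()].
#' @seealso [serialize_truth_tables()] for the inverse operation.
#' @export
parse_truth_table_dir <- function(path) {
  if (!dir.exists(path)) stop("not a directory: ", path)
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("no .csv truth tables found in ", path)
  rules <- list()
  for (f in files) {
    nm <- sub("\\.csv$", "", basename(f))
    tab <- utils::read.table(f, header = TRUE, sep = ",", check.names = FALSE,
                             colClasses = "integer", strip.white = TRUE)
    if (ncol(tab) == 1 && grepl("\t", readLines(f, n = 1)))
      tab <- utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE,
                               colClasses = "integer", strip.white = TRUE)
    cols <- names(tab)
    if (cols[length(cols)] != nm)
      stop(f, ": last header column must be the node name '", nm, "'")
    inputs <- cols[-length(cols)]
    k <- length(inputs)
    if (nrow(tab) != 2^k)
      stop(f, ": ", nrow(tab), " rows, expected 2^", k, " = ", 2^k)
    out <- tab[[length(cols)]]
    if (anyNA(out) || !all(out %in% c(0L, 1L)))
      stop(f, ": output column must contain only 0/1")
    if (k > 0) {
      # positional indexing: a self-input duplicates the node's column name
      bits <- as.matrix(tab[, seq_len(k), drop = FALSE])
      if (anyNA(bits) || !all(bits %in% c(0L, 1L)))
        stop(f, ": input columns must contain only 0/1")
      idx <- as.vector(bits %*% 2^((k - 1):0)) + 1L
      if (anyDuplicated(idx))
        stop(f, ": duplicate assignment rows")
      table_vec <- integer(2^k)
      table_vec[idx] <- out
    } else {
      table_vec <- out
    }
    rules[[nm]] <- list(inputs = inputs, table = table_vec)
  }
  ext_file <- file.path(path, "external.txt")
  external <- if (file.exists(ext_file)) {
    e <- trimws(readLines(ext_file, warn = FALSE))
    e[nzchar(e)]
  } else character()
  known <- c(names(rules), external)
  for (nm in names(rules)) {
    bad <- setdiff(rules[[nm]]$inputs, known)
    if (length(bad) > 0)
      stop("table for '", nm, "' references unresolved input '", bad[1], "'")
  }
  node_file <- file.path(path, "nodes.txt")
  nodes <- if (file.exists(node_file)) {
    v <- trimws(readLines(node_file, warn = FALSE))
    v[nzchar(v)]
  } else NULL
  boolean_network(rules = rules, external = external, nodes = nodes)
}

#' Write a Boolean network as a truth-table directory
#'
#' Writes one `<node>.csv` per regulated node (rows in canonical ascending
#' binary order), `external.txt` with the input-only nodes, and `nodes.txt`
#' recording the node order so that [parse_truth_table_dir()] reconstructs an
#' identical network.
#'
#' @param net a `boolean_network`.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
serialize_truth_tables <- function(net, path) {
  validate_network(net)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create directory: ", path)
  for (nm in names(net$rules)) {
    r <- net$rules[[nm]]
    k <- length(r$inputs)
    # cbind, not data.frame assignment: a self-input shares the node's name
    m <- cbind(rule_assignments(k), r$table)
    colnames(m) <- c(r$inputs, nm)
    utils::write.table(m, file.path(path, paste0(nm, ".csv")), sep = ",",
                       row.names = FALSE, col.names = TRUE, quote = FALSE)
  }
  writeLines(external_nodes(net), file.path(path, "external.txt"))
  writeLines(net$nodes, file.path(path, "nodes.txt"))
  invisible(path)
}

#' Wiring digraph of a Boolean network
#'
#' Builds the directed graph with an edge `j -> i` whenever `j` is listed as
#' an input of `i`'s rule. Self-loops (a node appearing in its own input
#' list) are kept or dropped according to `include_self`; path-based measures
#' exclude them, degree counts include them.
#'
#' @param net a `boolean_network`.
#' @param include_self keep self-loop edges?
#' @return an `igraph` directed graph whose vertices are the network nodes in
#'   order.
#' @export
wiring_graph <- function(net, include_self = TRUE) {
  edges <- do.call(rbind, c(list(data.frame(from = character(), to = character())),
    lapply(names(net$rules), function(nm) {
      data.frame(from = net$rules[[nm]]$inputs, to = nm,
                 stringsAsFactors = FALSE)
    })))
  if (!include_self) edges <- edges[edges$from != edges$to, , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = net$nodes)
}

#' Export the wiring digraph for visualization tools
#'
#' @param net a `boolean_network`.
#' @param file output path.
#' @param format `"graphml"` or `"dot"`.
#' @return `file`, invisibly.
#' @export
export_graph <- function(net, file, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(wiring_graph(net), file, format = format)
  invisible(file)
}
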