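#' @useDynLib logiprofile, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom dplyr %>%
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Tokenizer shared by the BND and CFG dialects
# ---------------------------------------------------------------------------

lp_tokenize <- function(text) {
  # strip // and # comments line-wise, keep positions
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) lines <- ""
  toks <- list()
  pat <- paste0(
    "(\\$[A-Za-z_][A-Za-z0-9_]*)|",  # CFG-style symbolic variable
    "([A-Za-z_][A-Za-z0-9_.]*)|",    # identifier (dots allowed for CFG keys)
    "(-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)|", # number (sign for CFG values)
    "(&&|\\|\\||[][&|!(){};=?:@,])"          # punctuation
  )
  for (ln in seq_along(lines)) {
    line <- sub("(//|#).*$", "", lines[[ln]])
    pos <- 1L
    while (pos <= nchar(line)) {
      rest <- substr(line, pos, nchar(line))
      ws <- regmatches(rest, regexpr("^[ \t\r]+", rest))
      if (length(ws) == 1L) {
        pos <- pos + nchar(ws)
        next
      }
      m <- regmatches(rest, regexpr(paste0("^(", pat, ")"), rest))
      if (length(m) == 0L) {
        stop(sprintf("syntax error at line %d, column %d: unexpected character '%s'",
                     ln, pos, substr(rest, 1, 1)), call. = FALSE)
      }
      toks[[length(toks) + 1L]] <- list(text = m, line = ln, col = pos)
      pos <- pos + nchar(m)
    }
  }
  toks
}

lp_tok_err <- function(tok, msg) {
  if (is.null(tok)) stop(sprintf("syntax error at end of input: %s", msg), call. = FALSE)
  stop(sprintf("syntax error at line %d, column %d: %s (near '%s')",
               tok$line, tok$col, msg, tok$text), call. = FALSE)
}

# cursor over a token list
lp_cursor <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env
}
lp_peek <- function(cur) if (cur$i <= length(cur$tokens)) cur$tokens[[cur$i]] else NULL
lp_next <- function(cur) {
  tok <- lp_peek(cur)
  cur$i <- cur$i + 1L
  tok
}
lp_expect <- function(cur, text) {
  tok <- lp_next(cur)
  if (is.null(tok) || tok$text != text) lp_tok_err(tok, sprintf("expected '%s'", text))
  tok
}

# ---------------------------------------------------------------------------
# Boolean rule expressions
# ---------------------------------------------------------------------------

rule_var   <- function(name) structure(list(op = "var", name = name), class = "rule_ast")
rule_const <- function(value) structure(list(op = "const", value = as.integer(value)), class = "rule_ast")
rule_not   <- function(x) structure(list(op = "not", x = x), class = "rule_ast")
rule_and   <- function(a, b) structure(list(op = "and", lhs = a, rhs = b), class = "rule_ast")
rule_or    <- function(a, b) structure(list(op = "or", lhs = a, rhs = b), class = "rule_ast")

#' Parse a Boolean rule expression
#'
#' Grammar: `OR` has the lowest precedence, then `AND`, then `NOT`;
#' parentheses group. Operator spellings `!`/`NOT`, `&`/`&&`/`AND`,
#' `|`/`||`/`OR` are accepted, keywords case-insensitively. Literals `0`
#' and `1` are constants; anything else is a node identifier.
#'
#' @param text rule source, e.g. `"A & !(B | C)"`.
#' @return a rule AST (class `rule_ast`).
#' @examples
#' parse_rule("A & !B")
#' @export
parse_rule <- function(text) {
  cur <- lp_cursor(lp_tokenize(text))
  ast <- lp_parse_or(cur)
  tok <- lp_peek(cur)
  if (!is.null(tok)) lp_tok_err(tok, "trailing input after expression")
  ast
}

lp_is_kw <- function(tok, kw) !is.null(tok) && toupper(tok$text) == kw

lp_parse_or <- function(cur) {
  lhs <- lp_parse_and(cur)
  repeat {
    tok <- lp_peek(cur)
    if (!is.null(tok) && (tok$text %in% c("|", "||") || lp_is_kw(tok, "OR"))) {
      lp_next(cur)
      lhs <- rule_or(lhs, lp_parse_and(cur))
    } else {
      return(lhs)
    }
  }
}

lp_parse_and <- function(cur) {
  lhs <- lp_parse_not(cur)
  repeat {
    tok <- lp_peek(cur)
    if (!is.null(tok) && (tok$text %in% c("&", "&&") || lp_is_kw(tok, "AND"))) {
      lp_next(cur)
      lhs <- rule_and(lhs, lp_parse_not(cur))
    } else {
      return(lhs)
    }
  }
}

lp_parse_not <- function(cur) {
  tok <- lp_peek(cur)
  if (!is.null(tok) && (tok$text == "!" || lp_is_kw(tok, "NOT"))) {
    lp_next(cur)
    return(rule_not(lp_parse_not(cur)))
  }
  lp_parse_atom(cur)
}

lp_parse_atom <- function(cur) {
  tok <- lp_next(cur)
  if (is.null(tok)) lp_tok_err(tok, "expected an identifier, constant or '('")
  if (tok$text == "(") {
    inner <- lp_parse_or(cur)
    lp_expect(cur, ")")
    return(inner)
  }
  if (tok$text %in% c("0", "1")) return(rule_const(tok$text))
  if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", tok$text)) {
    if (toupper(tok$text) %in% c("AND", "OR", "NOT"))
      lp_tok_err(tok, "operator keyword used as identifier")
    return(rule_var(tok$text))
  }
  lp_tok_err(tok, "expected an identifier, constant or '('")
}

#' Evaluate a Boolean rule on a complete network state
#'
#' @param rule a `rule_ast` from [parse_rule()] or a model's `rules` list.
#' @param state named logical or 0/1 vector assigning every node referenced
#'   by the rule.
#' @return 0 or 1.
#' @examples
#' evaluate_rule(parse_rule("!A"), c(A = 1))
#' @export
evaluate_rule <- function(rule, state) {
  v <- switch(rule$op,
    const = rule$value == 1L,
    var   = {
      if (!rule$name %in% names(state))
        stop(sprintf("incomplete state: node '%s' unassigned", rule$name), call. = FALSE)
      as.logical(state[[rule$name]])
    },
    not   = !evaluate_rule(rule$x, state),
    and   = evaluate_rule(rule$lhs, state) && evaluate_rule(rule$rhs, state),
    or    = evaluate_rule(rule$lhs, state) || evaluate_rule(rule$rhs, state),
    stop("unknown rule operator: ", rule$op)
  )
  as.integer(v)
}

rule_vars <- function(rule) {
  switch(rule$op,
    const = character(0),
    var   = rule$name,
    not   = rule_vars(rule$x),
    unique(c(rule_vars(rule$lhs), rule_vars(rule$rhs)))
  )
}

#' @export
format.rule_ast <- function(x, ...) deparse_rule(x, parent = "or")

# parenthesize only when precedence requires it
deparse_rule <- function(rule, parent = "or") {
  prec <- c(or = 1L, and = 2L, not = 3L, var = 4L, const = 4L)
  s <- switch(rule$op,
    const = as.character(rule$value),
    var   = rule$name,
    not   = paste0("!", deparse_rule(rule$x, "not")),
    and   = paste(deparse_rule(rule$lhs, "and"), "&", deparse_rule(rule$rhs, "and")),
    or    = paste(deparse_rule(rule$lhs, "or"), "|", deparse_rule(rule$rhs, "or"))
  )
  if (prec[[rule$op]] < prec[[parent]] ||
      (rule$op == "and" && parent == "not") || (rule$op == "or" && parent == "not")) {
    s <- paste0("(", s, ")")
  }
  s
}

#' @export
print.rule_ast <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# compile an AST to postfix bytecode for the C++ engine and the vectorized
# evaluator: positive k pushes node k's value, -1 NOT, -2 AND, -3 OR,
# -4 literal 0, -5 literal 1
compile_rule <- function(rule, node_index) {
  switch(rule$op,
    const = if (rule$value == 1L) -5L else -4L,
    var   = node_index[[rule$name]],
    not   = c(compile_rule(rule$x, node_index), -1L),
    and   = c(compile_rule(rule$lhs, node_index), compile_rule(rule$rhs, node_index), -2L),
    or    = c(compile_rule(rule$lhs, node_index), compile_rule(rule$rhs, node_index), -3L)
  )
}

compile_rules <- function(model) {
  idx <- stats::setNames(seq_along(model$nodes), model$nodes)
  lapply(model$rules[model$nodes], compile_rule, node_index = idx)
}

# vectorized bytecode evaluation over a 0/1 state matrix (rows = states)
eval_rule_matrix <- function(code, states) {
  stack <- vector("list", 8L)
  top <- 0L
  for (op in code) {
    if (op > 0L) {
      top <- top + 1L
      stack[[top]] <- states[, op] != 0L
    } else if (op == -1L) {
      stack[[top]] <- !stack[[top]]
    } else if (op == -2L) {
      stack[[top - 1L]] <- stack[[top - 1L]] & stack[[top]]
      top <- top - 1L
    } else if (op == -3L) {
      stack[[top - 1L]] <- stack[[top - 1L]] | stack[[top]]
      top <- top - 1L
    } else if (op == -4L) {
      top <- top + 1L
      stack[[top]] <- rep(FALSE, nrow(states))
    } else if (op == -5L) {
      top <- top + 1L
      stack[[top]] <- rep(TRUE, nrow(states))
    }
  }
  stack[[1L]]
}

# ---------------------------------------------------------------------------
# Logical model (BND dialect)
# ---------------------------------------------------------------------------

new_logical_model <- function(nodes, rules, outputs = character(0),
                              bnd_rates = NULL) {
  structure(
    list(nodes = nodes, rules = rules, outputs = outputs, bnd_rates = bnd_rates),
    class = "logical_model"
  )
}

#' Parse a logical model from BND-dialect text
#'
#' The dialect is a MaBoSS-style list of node blocks:
#' ```
#' node A {
#'   logic = A;
#' }
#' node B {
#'   logic = A & !C;
#'   rate_up = 2;          // optional scalar rates
#'   rate_down = 0.5;
#' }
#' ```
#' The reference tool's conditional rate syntax
#' `rate_up = @logic ? $u : 0;` is normalized at parse time into the scalar
#' up/down pair (the non-`@logic` branch must be 0 and symbolic `$`
#' variables default to 1). Every identifier used in a rule must be a
#' declared node; input nodes carry the self-rule `logic = A;`.
#'
#' @param text BND source as a single string, or a file path.
#' @return a `logical_model`: node list, rule ASTs, any BND-level rates.
#' @seealso [write_bnd()], [parse_cfg()]
#' @examples
#' m <- parse_bnd("node A { logic = A; } node B { logic = !A; }")
#' m$nodes
#' @export
parse_bnd <- function(text) {
  text <- read_if_path(text)
  cur <- lp_cursor(lp_tokenize(text))
  nodes <- character(0)
  rules <- list()
  rates <- list()
  repeat {
    tok <- lp_peek(cur)
    if (is.null(tok)) break
    if (tolower(tok$text) != "node") lp_tok_err(tok, "expected 'node'")
    lp_next(cur)
    name_tok <- lp_next(cur)
    if (is.null(name_tok) || !grepl("^[A-Za-z_][A-Za-z0-9_]*$", name_tok$text))
      lp_tok_err(name_tok, "expected a node name")
    name <- name_tok$text
    if (name %in% nodes)
      lp_tok_err(name_tok, sprintf("duplicate node '%s'", name))
    lp_expect(cur, "{")
    attrs <- lp_parse_attrs(cur)
    nodes <- c(nodes, name)
    rules[[name]] <- lp_interpret_logic(attrs, name)
    rates[[name]] <- lp_interpret_rates(attrs, name)
  }
  if (length(nodes) == 0L) stop("empty model: no node blocks found", call. = FALSE)
  # referenced-node validation
  for (nm in nodes) {
    missing <- setdiff(rule_vars(rules[[nm]]), nodes)
    if (length(missing) > 0L) {
      stop(sprintf("rule of node '%s' references undeclared node(s): %s",
                   nm, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  bnd_rates <- dplyr::bind_rows(rates)
  new_logical_model(nodes, rules, bnd_rates = bnd_rates)
}

# read `name = tokens... ;` attributes until the closing brace
lp_parse_attrs <- function(cur) {
  attrs <- list()
  repeat {
    tok <- lp_next(cur)
    if (is.null(tok)) lp_tok_err(tok, "unterminated node block")
    if (tok$text == "}") return(attrs)
    if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", tok$text))
      lp_tok_err(tok, "expected an attribute name or '}'")
    key <- tolower(tok$text)
    lp_expect(cur, "=")
    val <- list()
    repeat {
      vt <- lp_next(cur)
      if (is.null(vt)) lp_tok_err(vt, "unterminated attribute (missing ';')")
      if (vt$text == ";") break
      val[[length(val) + 1L]] <- vt
    }
    attrs[[key]] <- val
  }
}

lp_interpret_logic <- function(attrs, name) {
  val <- attrs[["logic"]]
  if (is.null(val))
    stop(sprintf("node '%s' has no 'logic' attribute", name), call. = FALSE)
  cur <- lp_cursor(val)
  ast <- lp_parse_or(cur)
  if (!is.null(lp_peek(cur))) lp_tok_err(lp_peek(cur), "trailing input in logic expression")
  ast
}

# rate_up / rate_down: a numeric literal, `$var` (treated as 1), or the
# conditional `@logic ? x : 0` / `@logic ? 0 : x` normalized to a scalar
lp_interpret_rates <- function(attrs, name) {
  get_rate <- function(key, direction) {
    val <- attrs[[key]]
    if (is.null(val)) return(NA_real_)
    txt <- vapply(val, function(t) t$text, character(1))
    num <- function(s) {
      if (grepl("^\\$", s)) return(1)  # symbolic CFG variable; scalar default
      x <- suppressWarnings(as.numeric(s))
      if (is.na(x)) lp_tok_err(val[[1]], sprintf("cannot interpret %s of node '%s'", key, name))
      x
    }
    if (length(txt) == 1L) return(num(txt))
    # @ logic ? a : b  (tokenizer splits '@' and 'logic')
    qm <- which(txt == "?")
    cl <- which(txt == ":")
    if (length(qm) == 1L && length(cl) == 1L && cl > qm) {
      on_true  <- paste(txt[(qm + 1L):(cl - 1L)], collapse = "")
      on_false <- paste(txt[(cl + 1L):length(txt)], collapse = "")
      active_branch <- if (direction == "up") on_true else on_false
      other_branch  <- if (direction == "up") on_false else on_true
      other_num <- suppressWarnings(as.numeric(other_branch))
      if (is.na(other_num) || other_num != 0)
        lp_tok_err(val[[1]], sprintf("unsupported %s expression for node '%s'", key, name))
      return(num(active_branch))
    }
    lp_tok_err(val[[1]], sprintf("cannot interpret %s of node '%s'", key, name))
  }
  up <- get_rate("rate_up", "up")
  dn <- get_rate("rate_down", "down")
  if (!is.na(up) && up < 0) stop(sprintf("negative rate_up for node '%s'", name), call. = FALSE)
  if (!is.na(dn) && dn < 0) stop(sprintf("negative rate_down for node '%s'", name), call. = FALSE)
  tibble::tibble(node = name, rate_up = up, rate_down = dn)
}

read_if_path <- function(text) {
  if (length(text) == 1L && !grepl("[{\n=]", text) && file.exists(text)) {
    return(paste(readLines(text, warn = FALSE), collapse = "\n"))
  }
  paste(text, collapse = "\n")
}

#' Serialize a logical model to BND-dialect text
#'
#' @param model a `logical_model`.
#' @param path optional file to write; the text is returned invisibly then.
#' @return BND source text.
#' @export
write_bnd <- function(model, path = NULL) {
  blocks <- vapply(model$nodes, function(nm) {
    lines <- sprintf("  logic = %s;", format(model$rules[[nm]]))
    if (!is.null(model$bnd_rates)) {
      r <- model$bnd_rates[model$bnd_rates$node == nm, ]
      if (nrow(r) == 1L) {
        if (!is.na(r$rate_up))   lines <- c(lines, sprintf("  rate_up = %.17g;", r$rate_up))
        if (!is.na(r$rate_down)) lines <- c(lines, sprintf("  rate_down = %.17g;", r$rate_down))
      }
    }
    paste0("node ", nm, " {\n", paste(lines, collapse = "\n"), "\n}")
  }, character(1))
  text <- paste(blocks, collapse = "\n\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Designate phenotype read-out nodes
#'
#' Which nodes are phenotype read-outs is a property of the analysis, not of
#' the rule file; this records the choice on the model object.
#'
#' @param model a `logical_model`.
#' @param nodes character vector of node names.
#' @return the model with `outputs` set.
#' @export
set_outputs <- function(model, nodes) {
  missing <- setdiff(nodes, model$nodes)
  if (length(missing) > 0L)
    stop("unknown node(s): ", paste(missing, collapse = ", "), call. = FALSE)
  model$outputs <- nodes
  model
}

#' @export
print.logical_model <- function(x, ...) {
  cat(sprintf("<logical_model> %d nodes\n", length(x$nodes)))
  for (nm in x$nodes) cat(sprintf("  %s = %s\n", nm, format(x$rules[[nm]])))
  if (length(x$outputs)) cat("  read-outs:", paste(x$outputs, collapse = ", "), "\n")
  invisible(x)
}

#' Export a parsed model as JSON for interchange
#'
#' @param model a `logical_model`.
#' @param path optional output file.
#' @return JSON string (invisibly when `path` is given).
#' @export
model_to_json <- function(model, path = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON export", call. = FALSE)
  obj <- list(
    nodes = model$nodes,
    rules = lapply(model$rules[model$nodes], format),
    outputs = model$outputs
  )
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# ---------------------------------------------------------------------------
# Simulation settings (CFG dialect)
# ---------------------------------------------------------------------------

#' Default simulation settings for a model
#'
#' All transition rates are 1 and every node starts active with probability
#' 0.5 (a maximally uninformative heterogeneous population); BND-level
#' scalar rates, when present, seed the per-node rates.
#'
#' @param model a `logical_model`.
#' @param max_time simulated time horizon (time units).
#' @param n_trajectories ensemble size.
#' @param time_bins number of reporting bins over `[0, max_time]`.
#' @param seed master RNG seed.
#' @param asymptotic_window trailing fraction of `[0, max_time]` averaged
#'   for asymptotic probability estimates.
#' @return a `simulation_settings` object.
#' @export
default_settings <- function(model, max_time = 50, n_trajectories = 1000,
                             time_bins = 100, seed = 1L,
                             asymptotic_window = 0.1) {
  nodes <- tibble::tibble(
    node = model$nodes,
    istate = 0.5,
    k_up = 1,
    k_down = 1,
    is_internal = FALSE
  )
  if (!is.null(model$bnd_rates) && nrow(model$bnd_rates) > 0L) {
    m <- match(nodes$node, model$bnd_rates$node)
    up <- model$bnd_rates$rate_up[m]
    dn <- model$bnd_rates$rate_down[m]
    nodes$k_up[!is.na(up)] <- up[!is.na(up)]
    nodes$k_down[!is.na(dn)] <- dn[!is.na(dn)]
  }
  new_simulation_settings(nodes, max_time, n_trajectories, time_bins, seed,
                          asymptotic_window)
}

new_simulation_settings <- function(nodes, max_time, n_trajectories, time_bins,
                                    seed, asymptotic_window) {
  s <- structure(
    list(nodes = nodes, max_time = max_time,
         n_trajectories = as.integer(n_trajectories),
         time_bins = as.integer(time_bins), seed = as.integer(seed),
         asymptotic_window = asymptotic_window),
    class = "simulation_settings"
  )
  validate_settings(s)
  s
}

validate_settings <- function(s) {
  stopifnot(is.data.frame(s$nodes))
  if (any(s$nodes$istate < 0 | s$nodes$istate > 1))
    stop("initial-state probability outside [0, 1]", call. = FALSE)
  if (any(s$nodes$k_up < 0) || any(s$nodes$k_down < 0))
    stop("negative transition rate", call. = FALSE)
  if (!(s$max_time > 0)) stop("max_time must be positive", call. = FALSE)
  if (s$n_trajectories < 1L) stop("n_trajectories must be >= 1", call. = FALSE)
  if (s$time_bins < 1L) stop("time_bins must be >= 1", call. = FALSE)
  if (!(s$asymptotic_window > 0 && s$asymptotic_window <= 1))
    stop("asymptotic_window must lie in (0, 1]", call. = FALSE)
  invisible(s)
}

#' Parse simulation settings from CFG-dialect text
#'
#' Simple assignment dialect, one statement per line/semicolon:
#' ```
#' A.istate = 0.6;
#' A.rate_up = 2;  A.rate_down = 0.5;
#' A.is_internal = TRUE;
#' max_time = 50;  n_trajectories = 1000;  time_bins = 100;
#' seed = 42;  asymptotic_window = 0.1;
#' ```
#' Nodes not mentioned keep the defaults of [default_settings()].
#'
#' @param text CFG source (string or file path).
#' @param model the `logical_model` the settings refer to.
#' @inheritParams default_settings
#' @return a `simulation_settings` object.
#' @export
parse_cfg <- function(text, model) {
  s <- default_settings(model)
  text <- read_if_path(text)
  toks <- lp_tokenize(text)
  cur <- lp_cursor(toks)
  repeat {
    tok <- lp_next(cur)
    if (is.null(tok)) break
    key <- tok$text
    lp_expect(cur, "=")
    val_tok <- lp_next(cur)
    if (is.null(val_tok)) lp_tok_err(val_tok, "expected a value")
    # optional trailing ';'
    nxt <- lp_peek(cur)
    if (!is.null(nxt) && nxt$text == ";") lp_next(cur)
    if (grepl("\\.", key)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (length(parts) != 2L) lp_tok_err(tok, "expected '<node>.<attribute>'")
      node <- parts[1]
      attr <- tolower(parts[2])
      if (!node %in% model$nodes)
        lp_tok_err(tok, sprintf("unknown node '%s'", node))
      i <- match(node, s$nodes$node)
      if (attr == "is_internal") {
        s$nodes$is_internal[i] <- toupper(val_tok$text) %in% c("TRUE", "1")
        next
      }
      v <- suppressWarnings(as.numeric(val_tok$text))
      if (is.na(v)) lp_tok_err(val_tok, "expected a number")
      if (attr == "istate") {
        if (v < 0 || v > 1) lp_tok_err(val_tok, "istate outside [0, 1]")
        s$nodes$istate[i] <- v
      } else if (attr == "rate_up") {
        if (v < 0) lp_tok_err(val_tok, "negative rate")
        s$nodes$k_up[i] <- v
      } else if (attr == "rate_down") {
        if (v < 0) lp_tok_err(val_tok, "negative rate")
        s$nodes$k_down[i] <- v
      } else {
        lp_tok_err(tok, sprintf("unknown node attribute '%s'", attr))
      }
    } else {
      v <- suppressWarnings(as.numeric(val_tok$text))
      if (is.na(v)) lp_tok_err(val_tok, "expected a number")
      key <- tolower(key)
      if (key == "max_time") s$max_time <- v
      else if (key == "n_trajectories") s$n_trajectories <- as.integer(v)
      else if (key == "time_bins") s$time_bins <- as.integer(v)
      else if (key == "seed") s$seed <- as.integer(v)
      else if (key == "asymptotic_window") s$asymptotic_window <- v
      else lp_tok_err(tok, sprintf("unknown setting '%s'", key))
    }
  }
  validate_settings(s)
  s
}

#' Serialize simulation settings to CFG-dialect text
#'
#' Round-trips exactly through [parse_cfg()]: every node is listed with its
#' full-precision istate and rates.
#'
#' @param settings a `simulation_settings`.
#' @param model the matching `logical_model`.
#' @param path optional output file.
#' @return CFG text.
#' @export
write_cfg <- function(settings, model, path = NULL) {
  validate_settings(settings)
  missing <- setdiff(settings$nodes$node, model$nodes)
  if (length(missing) > 0L)
    stop("settings refer to node(s) absent from the model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  num <- function(x) sprintf("%.17g", x)
  lines <- character(0)
  for (i in seq_len(nrow(settings$nodes))) {
    n <- settings$nodes[i, ]
    lines <- c(lines,
      sprintf("%s.istate = %s;", n$node, num(n$istate)),
      sprintf("%s.rate_up = %s;", n$node, num(n$k_up)),
      sprintf("%s.rate_down = %s;", n$node, num(n$k_down)))
    if (isTRUE(n$is_internal))
      lines <- c(lines, sprintf("%s.is_internal = TRUE;", n$node))
  }
  lines <- c(lines,
    sprintf("max_time = %s;", num(settings$max_time)),
    sprintf("n_trajectories = %d;", settings$n_trajectories),
    sprintf("time_bins = %d;", settings$time_bins),
    sprintf("seed = %d;", settings$seed),
    sprintf("asymptotic_window = %s;", num(settings$asymptotic_window)))
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' @export
print.simulation_settings <- function(x, ...) {
  cat(sprintf(
    "<simulation_settings> %d nodes | max_time %g | %d trajectories | %d bins | seed %d\n",
    nrow(x$nodes), x$max_time, x$n_trajectories, x$time_bins, x$seed))
  nondefault <- x$nodes$istate != 0.5 | x$nodes$k_up != 1 | x$nodes$k_down != 1
  if (any(nondefault)) {
    cat("non-default nodes:\n")
    print(x$nodes[nondefault, ], n = 20)
  }
  invisible(x)
}

#' Validate a model/settings pair
#'
#' Checks the structural invariants: unique node names, total rules over
#' declared nodes, settings within range, no strictly dead nodes unless
#' frozen.
#'
#' @param model a `logical_model`.
#' @param settings optional `simulation_settings` to check against the model.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_model <- function(model, settings = NULL) {
  if (anyDuplicated(model$nodes)) stop("duplicate node names", call. = FALSE)
  if (!setequal(names(model$rules), model$nodes))
    stop("rules are not total over the declared nodes", call. = FALSE)
  for (nm in model$nodes) {
    missing <- setdiff(rule_vars(model$rules[[nm]]), model$nodes)
    if (length(missing) > 0L)
      stop(sprintf("rule of '%s' references undeclared node(s): %s",
                   nm, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(settings)) {
    validate_settings(settings)
    if (!setequal(settings$nodes$node, model$nodes))
      stop("settings and model disagree on the node set", call. = FALSE)
    dead <- settings$nodes$k_up == 0 & settings$nodes$k_down == 0 &
      !(settings$nodes$istate %in% c(0, 1))
    if (any(dead))
      stop("node(s) with both rates 0 but a non-degenerate initial state: ",
           paste(settings$nodes$node[dead], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
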