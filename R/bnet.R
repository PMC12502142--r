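# bnet reader/writer.
#
# Dialect: one "target, factor-expression" line per variable; expressions over
# !, &, | and parentheses with literals 0/1; "#" starts a comment; an optional
# "targets, factors" header line is ignored. Expressions are expanded to DNF
# syntactically (negation pushed to literals, conjunction distributed over
# disjunction); contradictory and duplicate clauses are dropped.

tokenize_expr <- function(text) {
  tokens <- list()
  i <- 1L
  chars <- strsplit(text, "")[[1L]]
  n <- length(chars)
  name_char <- function(ch) grepl("[A-Za-z0-9_.]", ch)
  while (i <= n) {
    ch <- chars[[i]]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("!", "&", "|", "(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch)
      i <- i + 1L
      next
    }
    if (name_char(ch)) {
      j <- i
      while (j <= n && name_char(chars[[j]])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      type <- if (word %in% c("0", "1")) "const" else "name"
      tokens[[length(tokens) + 1L]] <- list(type = type, value = word)
      i <- j
      next
    }
    stop("unexpected character '", ch, "' in expression: ", text, call. = FALSE)
  }
  tokens
}

# Recursive descent over: expr := term ('|' term)* ; term := factor ('&' factor)* ;
# factor := '!' factor | '(' expr ')' | name | 0 | 1
parse_expr <- function(text) {
  tokens <- tokenize_expr(text)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]]$type else "eof"
  take <- function(type) {
    if (peek() != type) {
      stop("syntax error in expression '", text, "': expected ", type,
           " near token ", pos, call. = FALSE)
    }
    tok <- tokens[[pos]]
    pos <<- pos + 1L
    tok
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (peek() == "|") {
      take("|")
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_factor())
    while (peek() == "&") {
      take("&")
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (t == "!") { take("!"); return(list(op = "not", arg = parse_factor())) }
    if (t == "(") { take("("); e <- parse_or(); take(")"); return(e) }
    if (t == "name") return(list(op = "var", name = take("name")$value))
    if (t == "const") return(list(op = "const", value = as.integer(take("const")$value)))
    stop("syntax error in expression '", text, "': unexpected ", t, call. = FALSE)
  }
  ast <- parse_or()
  if (peek() != "eof") {
    stop("syntax error in expression '", text, "': trailing tokens", call. = FALSE)
  }
  ast
}

# Merge two clauses; NULL when they contradict each other.
merge_clauses <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (length(common) > 0L && any(a[common] != b[common])) return(NULL)
  c(a, b[setdiff(names(b), names(a))])
}

dnf_product <- function(d1, d2) {
  out <- list()
  for (c1 in d1) {
    for (c2 in d2) {
      m <- merge_clauses(c1, c2)
      if (!is.null(m)) out[[length(out) + 1L]] <- m
    }
  }
  out
}

ast_to_dnf <- function(ast, negate = FALSE) {
  switch(ast$op,
    var = {
      sign <- if (negate) -1L else 1L
      list(setNames(sign, ast$name))
    },
    const = {
      v <- if (negate) 1L - ast$value else ast$value
      if (v == 1L) dnf_constant_1() else dnf_constant_0()
    },
    not = ast_to_dnf(ast$arg, !negate),
    or = {
      parts <- lapply(ast$args, ast_to_dnf, negate = negate)
      if (!negate) {
        do.call(c, parts)
      } else {
        Reduce(dnf_product, parts) # De Morgan: negated disjunction is a conjunction
      }
    },
    and = {
      parts <- lapply(ast$args, ast_to_dnf, negate = negate)
      if (!negate) Reduce(dnf_product, parts) else do.call(c, parts)
    },
    stop("internal: unknown ast op ", ast$op)
  )
}

#' Read a Boolean network from bnet text
#'
#' @param text either a path to a bnet file or a character vector of bnet
#'   lines ("name, expression"). A vector of length one containing a newline
#'   or a comma is treated as document text, otherwise as a path.
#' @return a [boolean_network()]
#' @export
read_bnet <- function(text) {
  lines <- if (length(text) == 1L && !grepl("[,\n]", text)) {
    if (!file.exists(text)) stop("cannot read bnet file: ", text, call. = FALSE)
    readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    text
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^targets\\s*,\\s*factors$", lines, ignore.case = TRUE)]
  if (length(lines) == 0L) stop("empty bnet document", call. = FALSE)

  comma <- regexpr(",", lines, fixed = TRUE)
  if (any(comma < 0L)) {
    stop("malformed bnet line (no comma): ", lines[comma < 0L][1L], call. = FALSE)
  }
  vars <- trimws(substr(lines, 1L, comma - 1L))
  exprs <- trimws(substring(lines, comma + 1L))
  if (anyDuplicated(vars)) {
    stop("duplicate definition for variable(s): ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "), call. = FALSE)
  }
  dnfs <- lapply(exprs, function(e) ast_to_dnf(parse_expr(e)))
  boolean_network(vars, setNames(dnfs, vars))
}

format_dnf <- function(dnf) {
  k <- dnf_const(dnf)
  if (!is.na(k)) return(as.character(k))
  clauses <- vapply(dnf, function(clause) {
    lits <- ifelse(clause > 0L, names(clause), paste0("!", names(clause)))
    paste(lits, collapse = " & ")
  }, "")
  paste(clauses, collapse = " | ")
}

#' Write a Boolean network as bnet text
#'
#' Round-trips: `read_bnet(write_bnet(net))` reproduces identical DNFs.
#'
#' @param net a `boolean_network`
#' @param file optional path; when `NULL` the document is returned invisibly
#'   as a character vector of lines.
#' @return character vector of bnet lines, invisibly when written to a file.
#' @export
write_bnet <- function(net, file = NULL) {
  lines <- unname(vapply(net$variables, function(v) {
    paste0(v, ", ", format_dnf(net$functions[[v]]))
  }, ""))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
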