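#' Select atoms with a small expression language
#'
#' The grammar supports the clauses `chain X`, `resid a-b` (inclusive,
#' single ids and comma lists allowed), `resname N`, `name N`, `element E`
#' and the keyword `water` (residues HOH/WAT/TIP3/SOL).  Clauses combine
#' with `and`, `or`, `not` and parentheses; `and` binds tighter than `or`.
#' Matching indices are returned in topology order, and an expression that
#' matches nothing yields an empty (but valid) selection.
#'
#' @param structure a [tec_structure()].
#' @param expression selection string, e.g.
#'   `"chain A and resid 1219-1265 and not water"`.
#' @return An object of class `atom_selection` with fields `expression`
#'   and `indices` (integer atom indices).
#' @examples
#' s <- build_toy_tec(toy_tec_params(seed = 1))
#' sel <- select_atoms(s, "chain A and name CA")
#' length(sel$indices)
#' @export
select_atoms <- function(structure, expression) {
  stopifnot(inherits(structure, "tec_structure"))
  toks <- tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(st, structure)
  if (st$pos <= nrow(toks))
    stop(sprintf("selection syntax error at position %d: unexpected '%s'",
                 toks$start[st$pos], toks$text[st$pos]))
  structure(list(expression = expression,
                 indices = which(mask)),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> \"%s\": %d atoms\n", x$expression,
              length(x$indices)))
  invisible(x)
}

tokenize_selection <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L)
    stop("selection expression must be a single string")
  chars <- strsplit(expression, "")[[1L]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(text = ch, start = i)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("[[:space:]()]", chars[j])) j <- j + 1L
    toks[[length(toks) + 1L]] <-
      list(text = paste(chars[i:(j - 1L)], collapse = ""), start = i)
    i <- j
  }
  data.frame(text = vapply(toks, `[[`, "", "text"),
             start = vapply(toks, `[[`, 1L, "start"),
             stringsAsFactors = FALSE)
}

peek_tok <- function(st) if (st$pos <= nrow(st$toks)) st$toks$text[st$pos] else NA_character_

take_tok <- function(st) {
  if (st$pos > nrow(st$toks)) stop("selection syntax error: unexpected end of expression")
  t <- st$toks[st$pos, ]
  st$pos <- st$pos + 1L
  t
}

parse_or <- function(st, structure) {
  mask <- parse_and(st, structure)
  while (!is.na(peek_tok(st)) && tolower(peek_tok(st)) == "or") {
    take_tok(st)
    mask <- mask | parse_and(st, structure)
  }
  mask
}

parse_and <- function(st, structure) {
  mask <- parse_not(st, structure)
  while (!is.na(peek_tok(st)) && tolower(peek_tok(st)) == "and") {
    take_tok(st)
    mask <- mask & parse_not(st, structure)
  }
  mask
}

parse_not <- function(st, structure) {
  if (!is.na(peek_tok(st)) && tolower(peek_tok(st)) == "not") {
    take_tok(st)
    return(!parse_not(st, structure))
  }
  parse_primary(st, structure)
}

parse_primary <- function(st, structure) {
  tok <- take_tok(st)
  a <- structure$atoms
  kw <- tolower(tok$text)
  if (tok$text == "(") {
    mask <- parse_or(st, structure)
    close <- take_tok(st)
    if (close$text != ")")
      stop(sprintf("selection syntax error at position %d: expected ')'",
                   close$start))
    return(mask)
  }
  if (kw == "water") return(is_water_atom(a))
  if (kw %in% c("chain", "resid", "resname", "name", "element")) {
    val <- take_tok(st)
    if (val$text %in% c("(", ")") ||
        tolower(val$text) %in% c("and", "or", "not"))
      stop(sprintf("selection syntax error at position %d: '%s' needs a value",
                   val$start, kw))
    vals <- strsplit(val$text, ",", fixed = TRUE)[[1L]]
    return(switch(kw,
      chain = a$chain %in% vals,
      resname = toupper(a$resname) %in% toupper(vals),
      name = a$name %in% normalize_atom_name(vals),
      element = toupper(a$element) %in% toupper(vals),
      resid = resid_mask(a, vals, val$start)))
  }
  stop(sprintf("selection syntax error at position %d: unexpected '%s'",
               tok$start, tok$text))
}

resid_mask <- function(atoms, vals, pos) {
  mask <- rep(FALSE, nrow(atoms))
  for (v in vals) {
    m <- regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", v)[[1L]]
    if (m[1L] == -1)
      stop(sprintf("selection syntax error at position %d: bad resid '%s'",
                   pos, v))
    parts <- regmatches(v, regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", v))[[1L]]
    lo <- as.integer(parts[2L])
    hi <- if (nzchar(parts[3L])) as.integer(parts[3L]) else lo
    mask <- mask | (atoms$resid >= lo & atoms$resid <= hi)
  }
  mask
}
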