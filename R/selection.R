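#' Select atoms with a small selection grammar
#'
#' Evaluates a selection expression against a topology and returns an
#' `atom_group` (sorted, duplicate-free 0-based atom ids). The grammar
#' understands:
#'
#' * `resid 63`, `resid 63 65 68`, `resid 60:70` -- residue numbers / ranges
#' * `resname ARG DHA` -- residue names
#' * `name CA C1` -- atom names
#' * `chain A` -- chain ids
#' * `protein`, `lipid` -- molecule kind
#' * `sidechain` -- heavy atoms excluding the backbone `N`, `CA`, `C`, `O`
#'   (glycine therefore has an empty sidechain)
#' * `backbone` -- the backbone `N`, `CA`, `C`, `O`
#' * `hydrogen`, `heavy` -- by element
#' * `and`, `or`, `not`, parentheses; `not` binds tightest, then `and`,
#'   then `or`
#'
#' An empty result is legal and produces a warning, not an error.
#'
#' @param topology A [topology()].
#' @param expression Selection string, e.g. `"resid 63 and sidechain"`.
#' @param label Optional label stored on the group (defaults to the
#'   expression).
#' @return An `atom_group`: list with `atom_id` (sorted integer vector),
#'   `label`, and the owning `topology`.
#' @examples
#' top <- topology(data.frame(
#'   atom_name = c("N", "CA", "C", "O", "CB"),
#'   residue_number = 63, residue_name = "ARG", chain_id = "A"
#' ))
#' select_atoms(top, "sidechain")$atom_id # 4 (CB only)
#' @export
select_atoms <- function(topology, expression, label = expression) {
  stopifnot(inherits(topology, "topology"))
  tokens <- sel_tokenize(expression)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  mask <- sel_parse_or(state, topology)
  if (state$pos <= length(tokens)) {
    stop("select_atoms(): unexpected token '", tokens[state$pos],
         "' at position ", state$pos, call. = FALSE)
  }
  ids <- sort(topology$atom_id[mask])
  if (length(ids) == 0) {
    warning("select_atoms(): '", expression, "' matched no atoms",
            call. = FALSE)
  }
  atom_group(topology, ids, label = label)
}

#' Construct an atom group directly from ids
#' @param topology A [topology()].
#' @param atom_id 0-based atom ids (must exist; duplicates removed).
#' @param label Group label.
#' @return An `atom_group`.
#' @export
atom_group <- function(topology, atom_id, label = "group") {
  atom_id <- sort(unique(as.integer(atom_id)))
  if (length(atom_id) > 0 &&
      (min(atom_id) < 0 || max(atom_id) >= nrow(topology))) {
    stop("atom_group(): atom ids out of range", call. = FALSE)
  }
  structure(list(topology = topology, atom_id = atom_id, label = label),
            class = "atom_group")
}

#' @export
print.atom_group <- function(x, ...) {
  cat(sprintf("<atom_group> '%s': %d atoms\n", x$label, length(x$atom_id)))
  invisible(x)
}

#' @export
length.atom_group <- function(x) length(x$atom_id)

sel_tokenize <- function(expression) {
  if (!is.character(expression) || length(expression) != 1) {
    stop("selection must be a single string", call. = FALSE)
  }
  expr <- gsub("([()])", " \\1 ", expression)
  tokens <- strsplit(trimws(expr), "\\s+")[[1]]
  tokens <- tokens[tokens != ""]
  if (length(tokens) == 0) stop("empty selection", call. = FALSE)
  ok <- grepl("^[A-Za-z0-9_':*-]+$|^[()]$", tokens)
  if (any(!ok)) {
    stop("select_atoms(): bad token '", tokens[which(!ok)[1]],
         "' at position ", which(!ok)[1], call. = FALSE)
  }
  tokens
}

sel_peek <- function(state) {
  if (state$pos > length(state$tokens)) NA_character_
  else state$tokens[state$pos]
}
sel_take <- function(state) {
  t <- sel_peek(state)
  state$pos <- state$pos + 1L
  t
}

sel_parse_or <- function(state, top) {
  left <- sel_parse_and(state, top)
  while (identical(tolower(sel_peek(state)), "or")) {
    sel_take(state)
    left <- left | sel_parse_and(state, top)
  }
  left
}

sel_parse_and <- function(state, top) {
  left <- sel_parse_unary(state, top)
  while (identical(tolower(sel_peek(state)), "and")) {
    sel_take(state)
    left <- left & sel_parse_unary(state, top)
  }
  left
}

sel_keywords <- c("and", "or", "not", "(", ")")

sel_parse_unary <- function(state, top) {
  t <- sel_peek(state)
  if (is.na(t)) {
    stop("select_atoms(): unexpected end of expression at position ",
         state$pos, call. = FALSE)
  }
  if (tolower(t) == "not") {
    sel_take(state)
    return(!sel_parse_unary(state, top))
  }
  if (t == "(") {
    sel_take(state)
    inner <- sel_parse_or(state, top)
    if (!identical(sel_take(state), ")")) {
      stop("select_atoms(): missing ')' at position ", state$pos - 1,
           call. = FALSE)
    }
    return(inner)
  }
  sel_parse_primary(state, top)
}

sel_is_h <- function(top) toupper(top$element) == "H"

sel_parse_primary <- function(state, top) {
  t <- tolower(sel_take(state))
  bb <- c("N", "CA", "C", "O")
  switch(
    t,
    protein = top$molecule_kind == "protein",
    lipid = top$molecule_kind == "lipid",
    sidechain = top$molecule_kind == "protein" &
      !toupper(top$atom_name) %in% bb & !sel_is_h(top),
    backbone = top$molecule_kind == "protein" &
      toupper(top$atom_name) %in% bb,
    hydrogen = sel_is_h(top),
    heavy = !sel_is_h(top),
    resid = top$residue_number %in% sel_values_int(state),
    resname = toupper(top$residue_name) %in% sel_values_chr(state),
    name = toupper(top$atom_name) %in% sel_values_chr(state),
    chain = toupper(top$chain_id) %in% sel_values_chr(state),
    stop("select_atoms(): unknown keyword '", t, "' at position ",
         state$pos - 1, call. = FALSE)
  )
}

# consume the run of value tokens following resid/resname/name/chain
sel_value_run <- function(state) {
  vals <- character(0)
  repeat {
    t <- sel_peek(state)
    if (is.na(t) || tolower(t) %in% sel_keywords) break
    vals <- c(vals, sel_take(state))
  }
  if (length(vals) == 0) {
    stop("select_atoms(): keyword needs at least one value at position ",
         state$pos, call. = FALSE)
  }
  vals
}

sel_values_chr <- function(state) toupper(sel_value_run(state))

sel_values_int <- function(state) {
  vals <- sel_value_run(state)
  out <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+:[0-9-]+$", v)) {
      r <- as.integer(strsplit(v, ":")[[1]])
      out <- c(out, seq(r[1], r[2]))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else {
      stop("select_atoms(): expected residue number, got '", v,
           "' at position ", state$pos - 1, call. = FALSE)
    }
  }
  out
}
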