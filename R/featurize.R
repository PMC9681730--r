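# Featurization: typed molecular graphs and linker SMILES token sequences.

POCKET_ELEMENTS <- c("C", "N", "O", "S")   # codes 0..3, other -> 4
LIGAND_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P") # 0..8, other -> 9
BOND_CODES <- c(single = 1L, double = 2L, triple = 3L,
                aromatic = 4L, amide = 5L)

#' Integer code of a protein-pocket atom
#'
#' Pocket nodes use a 5-symbol vocabulary: C, N, O, S map to 0..3 and every
#' other heavy element to 4. Hydrogens must be filtered before coding.
#' @param element chemical element symbol(s).
#' @return integer code(s) in 0..4.
#' @export
protein_atom_code <- function(element) {
  if (any(!is_heavy(element)))
    stop("hydrogen has no pocket atom code; filter hydrogens first")
  code <- match(element, POCKET_ELEMENTS) - 1L
  code[is.na(code)] <- 4L
  code
}

#' Integer code of a ligand atom
#'
#' Ligand nodes use a 10-symbol vocabulary: C, N, O, S, F, Cl, Br, I, P map
#' to 0..8 in that order and every other heavy element to 9.
#' @param element chemical element symbol(s).
#' @return integer code(s) in 0..9.
#' @export
ligand_atom_code <- function(element) {
  if (any(!is_heavy(element)))
    stop("hydrogen has no ligand atom code; filter hydrogens first")
  code <- match(element, LIGAND_ELEMENTS) - 1L
  code[is.na(code)] <- 9L
  code
}

#' Integer code of a normalized bond label
#'
#' single, double, triple, aromatic, amide map to 1..5.
#' @param label normalized bond label(s).
#' @return integer code(s) in 1..5.
#' @export
bond_code <- function(label) {
  code <- BOND_CODES[label]
  if (any(is.na(code)))
    stop("unknown bond label(s): ",
         paste(unique(label[is.na(code)]), collapse = ", "))
  unname(code)
}

#' Build a typed molecular graph
#'
#' Converts a `molecule_record` or `pocket_selection` into the integer graph
#' representation consumed by the graph-convolution branches: hydrogens are
#' dropped, node i is the i-th retained heavy atom coded through the pocket
#' or ligand vocabulary, and each bond becomes one undirected typed edge.
#' Atoms left without bonds are kept as isolated nodes.
#'
#' @param x a `molecule_record` or `pocket_selection`.
#' @param kind `"protein_pocket"` or `"ligand"`; selects the node vocabulary.
#' @return an object of class `molecular_graph`: list with `kind`,
#'   `node_codes` (integer vector), `edges` (data.frame i, j, code with
#'   1-based node indices, one row per undirected bond) and `node_count`.
#' @export
to_graph <- function(x, kind = c("protein_pocket", "ligand")) {
  kind <- match.arg(kind)
  if (inherits(x, "pocket_selection")) {
    atoms <- x$atoms; bonds <- x$bonds
  } else if (inherits(x, "molecule_record")) {
    atoms <- x$atoms; bonds <- x$bonds
  } else stop("x must be a molecule_record or pocket_selection")
  heavy <- which(is_heavy(atoms$element))
  if (length(heavy) == 0L) stop("no heavy atoms to build a graph from")
  map <- integer(nrow(atoms)); map[heavy] <- seq_along(heavy)
  el <- atoms$element[heavy]
  codes <- if (kind == "protein_pocket") protein_atom_code(el)
           else ligand_atom_code(el)
  edges <- data.frame(i = integer(0), j = integer(0), code = integer(0))
  if (nrow(bonds) > 0L) {
    keep <- bonds$i %in% heavy & bonds$j %in% heavy
    if (any(keep))
      edges <- data.frame(i = map[bonds$i[keep]], j = map[bonds$j[keep]],
                          code = bond_code(bonds$label[keep]))
  }
  structure(list(kind = kind, node_codes = as.integer(codes),
                 edges = edges, node_count = length(codes)),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph>", x$kind, "-", x$node_count, "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Dense adjacency matrix of a molecular graph
#'
#' Symmetric 0/1 matrix with zero diagonal; bond presence only (types live
#' on the edge list).
#' @param g a `molecular_graph`.
#' @return a `node_count` x `node_count` matrix.
#' @export
adjacency_matrix <- function(g) {
  A <- matrix(0, g$node_count, g$node_count)
  if (nrow(g$edges) > 0L) {
    A[cbind(g$edges$i, g$edges$j)] <- 1
    A[cbind(g$edges$j, g$edges$i)] <- 1
  }
  A
}

PAD_CODE <- 0L
OOV_CODE <- 40L
N_TABLE_CHARS <- 39L

#' Build a SMILES character-encoding table from a corpus
#'
#' Counts every character over the corpus and assigns codes 1..39 to the 39
#' most frequent characters in descending frequency order; frequency ties
#' are broken by Unicode code point, ascending, so the table is independent
#' of corpus order. Code 0 is reserved for padding and code 40 for every
#' character outside the table.
#'
#' @param corpus character vector of SMILES strings.
#' @return an object of class `encoding_table`: list with `char_to_code`
#'   (named integer vector), `pad_code` and `oov_code`.
#' @export
build_encoding_table <- function(corpus) {
  chars <- unlist(strsplit(corpus, "", fixed = TRUE), use.names = FALSE)
  if (length(chars) == 0L) stop("empty corpus")
  freq <- table(chars)
  if (length(freq) < N_TABLE_CHARS)
    stop("corpus has only ", length(freq), " distinct characters; ",
         N_TABLE_CHARS, " are required (short by ",
         N_TABLE_CHARS - length(freq), ")")
  cs <- names(freq)
  ord <- order(-as.integer(freq), vapply(cs, utf8ToInt, integer(1)))
  top <- cs[ord][seq_len(N_TABLE_CHARS)]
  encoding_table(top)
}

#' Construct an encoding table from a ranked character list
#'
#' @param ranked_chars exactly 39 distinct single characters; the k-th gets
#'   code k.
#' @return an `encoding_table`.
#' @export
encoding_table <- function(ranked_chars) {
  stopifnot(length(ranked_chars) == N_TABLE_CHARS,
            !anyDuplicated(ranked_chars),
            all(nchar(ranked_chars) == 1L))
  structure(list(
    char_to_code = stats::setNames(seq_len(N_TABLE_CHARS), ranked_chars),
    pad_code = PAD_CODE, oov_code = OOV_CODE), class = "encoding_table")
}

#' The package's default SMILES encoding table
#'
#' A fixed synthetic ranking of 39 SMILES characters in an order that
#' follows typical character frequencies of lead-like organic molecules
#' (aliphatic carbon first, then aromatic carbon, branching and ring-bond
#' syntax, heteroatoms, charges and stereo marks). It is a deterministic
#' stand-in for a corpus-derived table; tables built from a user corpus with
#' [build_encoding_table()] or loaded from JSON with [read_encoding_table()]
#' are drop-in replacements.
#' @return an `encoding_table`.
#' @export
default_encoding_table <- function() {
  ranked <- c("C", "c", "(", ")", "1", "O", "N", "2", "=", "n", "3", "F",
              "[", "]", "S", "l", "s", "o", "H", "#", "@", "+", "-", "4",
              "B", "r", "/", "5", "P", "\\", "I", "6", ".", "%", "7", "i",
              "e", "8", "9")
  encoding_table(ranked)
}

#' Serialize / load an encoding table as JSON
#' @param table an `encoding_table`.
#' @param path JSON file path.
#' @return `path` (write) or an `encoding_table` (read).
#' @export
write_encoding_table <- function(table, path) {
  jsonlite::write_json(as.list(table$char_to_code), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_encoding_table
#' @export
read_encoding_table <- function(path) {
  m <- jsonlite::read_json(path)
  codes <- as.integer(unlist(m))
  if (length(codes) != N_TABLE_CHARS || !setequal(codes, seq_len(N_TABLE_CHARS)))
    stop("encoding table JSON must map 39 characters to codes 1..39")
  encoding_table(names(m)[order(codes)])
}

#' Tokenize a linker SMILES string
#'
#' Character-by-character lookup in the encoding table: in-table characters
#' get their code, every other character code 40; the sequence is
#' right-padded with 0 to `max_len`, and longer strings are truncated with
#' a warning. An empty string yields a valid all-pad sequence (an ablated
#' linker).
#'
#' @param smiles a SMILES string.
#' @param table an `encoding_table`.
#' @param max_len fixed output length, default 100.
#' @return an object of class `token_sequence`: list with `codes`
#'   (integer vector of length `max_len`) and `true_length`.
#' @export
tokenize <- function(smiles, table = default_encoding_table(),
                     max_len = 100L) {
  stopifnot(max_len >= 1L, inherits(table, "encoding_table"))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  if (length(chars) > max_len) {
    warning("SMILES of length ", length(chars), " truncated to ", max_len)
    chars <- chars[seq_len(max_len)]
  }
  codes <- unname(table$char_to_code[chars])
  codes[is.na(codes)] <- table$oov_code
  out <- rep(table$pad_code, max_len)
  if (length(codes)) out[seq_along(codes)] <- codes
  structure(list(codes = as.integer(out),
                 true_length = length(chars)), class = "token_sequence")
}

#' Decode a token sequence back to characters
#'
#' Inverse of [tokenize()] over in-table characters; pads are dropped and
#' out-of-vocabulary codes render as `"?"`.
#' @param tokens a `token_sequence`.
#' @param table the `encoding_table` used to encode.
#' @return a character string.
#' @export
detokenize <- function(tokens, table = default_encoding_table()) {
  codes <- tokens$codes[seq_len(tokens$true_length)]
  inv <- names(table$char_to_code)[order(table$char_to_code)]
  paste(ifelse(codes == table$oov_code, "?", inv[codes]), collapse = "")
}

#' Serialize a molecular graph as JSON
#' @param g a `molecular_graph`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(g, path) {
  jsonlite::write_json(
    list(kind = g$kind, node_codes = g$node_codes,
         edges = lapply(seq_len(nrow(g$edges)), function(k)
           c(g$edges$i[k], g$edges$j[k], g$edges$code[k]))),
    path, auto_unbox = TRUE)
  invisible(path)
}
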