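# The normative plain-text model-folder dialect of this package
# (cupSODA-compatible file naming):
#   left_side   M x N reactant stoichiometry matrix (mandatory)
#   right_side  M x N product stoichiometry matrix (mandatory)
#   c_vector    M kinetic constants, one per line (mandatory)
#   M_0         single initial-state row of N values (mandatory)
#   MX_0        R x N batch of initial states (optional)
#   c_matrix    R x M batch of kinetic constants (optional)
#   t_vector    output times, one per line, strictly increasing (optional)
#   cs_vector   0-based indices of species to save, one per line (optional;
#               default: all species)
#   alphabet    species names, one per line (optional)
# Values are tab- or space-separated, UTF-8, '.' decimal point, scientific
# notation accepted; blank lines are ignored.

read_numeric_table <- function(path, what) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1]]))
    if (any(is.na(v)))
      stop(sprintf("parse error in %s, line %d: non-numeric value",
                   what, i), call. = FALSE)
    v
  })
  if (length(rows) == 0)
    stop(sprintf("parse error in %s: file is empty", what), call. = FALSE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1)
    stop(sprintf("parse error in %s, line %d: expected %d values, found %d",
                 what, which(ncols != ncols[1])[1], ncols[1],
                 ncols[ncols != ncols[1]][1]), call. = FALSE)
  do.call(rbind, rows)
}

#' Read a model folder
#'
#' Parses the plain-text model-folder dialect documented in the package
#' (files `left_side`, `right_side`, `c_vector`, `M_0` mandatory;
#' `MX_0`, `c_matrix`, `t_vector`, `cs_vector`, `alphabet` optional).
#' Missing optional files take their documented defaults: all species
#' saved, a single parameterization taken from `M_0` and `c_vector`, no
#' output grid.
#'
#' @param folder path to the model folder.
#' @return list with elements `rbm` (an [rbm()]), `params` (a
#'   [parameterization_set()]), `t_out` (numeric vector or `NULL`) and
#'   `species_to_save` (1-based indices).
#' @export
read_biosimware <- function(folder) {
  if (!dir.exists(folder))
    stop(sprintf("model folder not found: %s", folder), call. = FALSE)
  need <- function(name) {
    p <- file.path(folder, name)
    if (!file.exists(p))
      stop(sprintf("missing mandatory model file: %s", name), call. = FALSE)
    p
  }
  opt <- function(name) {
    p <- file.path(folder, name)
    if (file.exists(p)) p else NULL
  }
  A <- read_numeric_table(need("left_side"), "left_side")
  B <- read_numeric_table(need("right_side"), "right_side")
  K <- drop(read_numeric_table(need("c_vector"), "c_vector"))
  X0 <- drop(read_numeric_table(need("M_0"), "M_0"))
  if (!all(dim(A) == dim(B)))
    stop(sprintf("dimension inconsistency: left_side is %dx%d but right_side is %dx%d",
                 nrow(A), ncol(A), nrow(B), ncol(B)), call. = FALSE)
  M <- nrow(A); N <- ncol(A)
  if (length(K) != M)
    stop(sprintf("dimension inconsistency: c_vector has %d entries, left_side has %d reactions",
                 length(K), M), call. = FALSE)
  if (length(X0) != N)
    stop(sprintf("dimension inconsistency: M_0 has %d entries, left_side has %d species",
                 length(X0), N), call. = FALSE)
  species <- NULL
  if (!is.null(p <- opt("alphabet"))) {
    species <- trimws(readLines(p, warn = FALSE))
    species <- species[nzchar(species)]
    if (length(species) != N)
      stop(sprintf("dimension inconsistency: alphabet has %d names, expected %d",
                   length(species), N), call. = FALSE)
  }
  m <- rbm(A, B, K, X0, species = species)
  X0_batch <- if (!is.null(p <- opt("MX_0"))) {
    xb <- read_numeric_table(p, "MX_0")
    if (ncol(xb) != N)
      stop(sprintf("dimension inconsistency: MX_0 has %d columns, expected %d",
                   ncol(xb), N), call. = FALSE)
    xb
  } else {
    matrix(X0, 1, N)
  }
  K_batch <- if (!is.null(p <- opt("c_matrix"))) {
    kb <- read_numeric_table(p, "c_matrix")
    if (ncol(kb) != M)
      stop(sprintf("dimension inconsistency: c_matrix has %d columns, expected %d",
                   ncol(kb), M), call. = FALSE)
    if (nrow(kb) != nrow(X0_batch))
      stop(sprintf("dimension inconsistency: c_matrix has %d rows but MX_0 has %d",
                   nrow(kb), nrow(X0_batch)), call. = FALSE)
    kb
  } else {
    NULL
  }
  t_out <- if (!is.null(p <- opt("t_vector"))) {
    tv <- drop(read_numeric_table(p, "t_vector"))
    if (any(diff(tv) <= 0))
      stop("parse error in t_vector: times must be strictly increasing",
           call. = FALSE)
    tv
  } else {
    NULL
  }
  save_idx <- if (!is.null(p <- opt("cs_vector"))) {
    # 0-based on disk, 1-based in memory
    idx <- drop(read_numeric_table(p, "cs_vector")) + 1L
    if (any(idx < 1 | idx > N))
      stop("parse error in cs_vector: species index out of range", call. = FALSE)
    as.integer(idx)
  } else {
    seq_len(N)
  }
  list(rbm = m, params = parameterization_set(X0_batch, K_batch),
       t_out = t_out, species_to_save = save_idx)
}

fmt_num <- function(x) sprintf("%.17g", x)

write_numeric_table <- function(x, path) {
  x <- as.matrix(x)
  writeLines(apply(x, 1, function(r) paste(fmt_num(r), collapse = "\t")), path)
}

#' Write a model folder
#'
#' Emits the plain-text dialect read by [read_biosimware()] with 17
#' significant digits, so a write/read round trip reproduces the model
#' exactly.
#'
#' @param rbm an [rbm()] object.
#' @param folder output directory (created if needed).
#' @param params optional [parameterization_set()]; writes `MX_0` (and
#'   `c_matrix` when per-row kinetics are present).
#' @param t_out optional output-time grid, written to `t_vector`.
#' @param species_to_save optional 1-based indices written 0-based to
#'   `cs_vector`.
#' @return the folder path, invisibly.
#' @export
write_biosimware <- function(rbm, folder, params = NULL, t_out = NULL,
                             species_to_save = NULL) {
  stopifnot(inherits(rbm, "rbm"))
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(folder))
    stop(sprintf("cannot create model folder: %s", folder), call. = FALSE)
  write_numeric_table(rbm$A, file.path(folder, "left_side"))
  write_numeric_table(rbm$B, file.path(folder, "right_side"))
  writeLines(fmt_num(rbm$K), file.path(folder, "c_vector"))
  write_numeric_table(matrix(rbm$X0, 1), file.path(folder, "M_0"))
  writeLines(rbm$species, file.path(folder, "alphabet"))
  if (!is.null(params)) {
    write_numeric_table(params$X0_batch, file.path(folder, "MX_0"))
    if (!is.null(params$K_batch))
      write_numeric_table(params$K_batch, file.path(folder, "c_matrix"))
  }
  if (!is.null(t_out))
    writeLines(fmt_num(t_out), file.path(folder, "t_vector"))
  if (!is.null(species_to_save))
    writeLines(as.character(as.integer(species_to_save) - 1L),
               file.path(folder, "cs_vector"))
  invisible(folder)
}

#' Write batch dynamics to tab-separated files
#'
#' One TSV per simulation (`dynamics_<r>.tsv`: first column `time`, one
#' column per saved species, header row of names) plus a batch summary
#' `summary.tsv` with per-row status, solver and spectral-radius estimate.
#' Values carry 17 significant digits so re-reading reproduces the states
#' to full double precision.
#'
#' @param result a `batch_result` from [run_batch()].
#' @param folder output directory.
#' @param species_to_save 1-based indices of species to write; an empty or
#'   `NULL` selection defaults to all species.
#' @return the folder path, invisibly.
#' @export
write_dynamics <- function(result, folder, species_to_save = NULL) {
  stopifnot(inherits(result, "batch_result"))
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  ntr <- length(result$trajectories)
  width <- nchar(as.character(ntr))
  for (r in seq_len(ntr)) {
    tr <- result$trajectories[[r]]
    idx <- species_to_save
    if (is.null(idx) || length(idx) == 0) idx <- seq_len(ncol(tr$states))
    d <- cbind(tr$times, tr$states[, idx, drop = FALSE])
    lines <- c(paste(c("time", tr$species[idx]), collapse = "\t"),
               apply(d, 1, function(row) paste(fmt_num(row), collapse = "\t")))
    writeLines(lines, file.path(folder, sprintf(
      paste0("dynamics_%0", width, "d.tsv"), r)))
  }
  summ <- glance.batch_result(result)
  lines <- c(paste(names(summ), collapse = "\t"),
             apply(summ, 1, function(row) paste(trimws(row), collapse = "\t")))
  writeLines(lines, file.path(folder, "summary.tsv"))
  invisible(folder)
}

#' Import a mass-action SBML model
#'
#' Reads an SBML (level 2 or 3) file whose reactions all follow mass-action
#' kinetics with a single rate constant each. The kinetic law of every
#' reaction must be, structurally, a product of one rate-constant
#' parameter, the reactant species raised to their stoichiometries, and
#' optionally a compartment identifier. Reversible reactions whose law is
#' a difference of two such terms are split into a forward and a backward
#' irreversible reaction. Any other rate law (e.g. Michaelis-Menten) is
#' rejected with an error naming the reaction. Initial state is taken
#' from `initialConcentration` (or `initialAmount`) attributes.
#'
#' @param file path to the SBML file.
#' @return an [rbm()] object.
#' @export
import_sbml <- function(file) {
  if (!file.exists(file)) stop(sprintf("SBML file not found: %s", file),
                               call. = FALSE)
  doc <- xml2::read_xml(file)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0) stop("SBML model has no species", call. = FALSE)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  x0 <- as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration"))
  amt <- as.numeric(xml2::xml_attr(sp_nodes, "initialAmount"))
  x0[is.na(x0)] <- amt[is.na(x0)]
  x0[is.na(x0)] <- 0
  comp_id <- xml2::xml_attr(xml2::xml_find_all(doc, ".//listOfCompartments/compartment"),
                            "id")
  gpar <- xml2::xml_find_all(doc, ".//model/listOfParameters/parameter")
  gpar_id <- xml2::xml_attr(gpar, "id")
  gpar_val <- as.numeric(xml2::xml_attr(gpar, "value"))
  names(gpar_val) <- gpar_id

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0) stop("SBML model has no reactions", call. = FALSE)
  N <- length(sp_id)
  rows_A <- list(); rows_B <- list(); ks <- numeric(0)

  stoich_row <- function(rx, side) {
    refs <- xml2::xml_find_all(rx, sprintf("./%s/speciesReference", side))
    row <- rep(0, N)
    for (ref in refs) {
      sid <- xml2::xml_attr(ref, "species")
      st <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      if (is.na(st)) st <- 1
      j <- match(sid, sp_id)
      if (is.na(j)) stop(sprintf("unknown species '%s' in reaction '%s'",
                                 sid, xml2::xml_attr(rx, "id")), call. = FALSE)
      row[j] <- row[j] + st
    }
    row
  }

  for (rx in rx_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    a_row <- stoich_row(rx, "listOfReactants")
    b_row <- stoich_row(rx, "listOfProducts")
    math <- xml2::xml_find_first(rx, "./kineticLaw/math")
    if (inherits(math, "xml_missing"))
      stop(sprintf("reaction '%s' has no kinetic law", rid), call. = FALSE)
    lpar <- xml2::xml_find_all(rx, "./kineticLaw//parameter | ./kineticLaw//localParameter")
    lpar_val <- as.numeric(xml2::xml_attr(lpar, "value"))
    names(lpar_val) <- xml2::xml_attr(lpar, "id")
    par_val <- c(lpar_val, gpar_val)
    terms <- parse_mass_action_math(xml2::xml_find_first(math, "./*"), rid)
    reversible <- identical(xml2::xml_attr(rx, "reversible"), "true")
    if (length(terms) == 2 && !reversible)
      stop(sprintf("reaction '%s': two-term rate law on an irreversible reaction",
                   rid), call. = FALSE)
    check_term <- function(term, a_side) {
      ks_in <- intersect(term$ci, names(par_val))
      sp_in <- term$ci[term$ci %in% sp_id]
      other <- setdiff(term$ci, c(names(par_val), sp_id, comp_id))
      if (length(ks_in) != 1 || length(other) > 0)
        stop(sprintf("unsupported (non-mass-action) kinetic law in reaction '%s'",
                     rid), call. = FALSE)
      # species powers must match the stoichiometry of the consuming side
      pow <- rep(0, N)
      for (nm in names(term$pow)) {
        j <- match(nm, sp_id)
        if (!is.na(j)) pow[j] <- term$pow[[nm]]
      }
      for (s in sp_in) {
        j <- match(s, sp_id)
        if (pow[j] == 0) pow[j] <- 1
      }
      if (!isTRUE(all.equal(pow, a_side)))
        stop(sprintf("unsupported (non-mass-action) kinetic law in reaction '%s': species powers do not match stoichiometry",
                     rid), call. = FALSE)
      unname(par_val[ks_in])
    }
    k_fwd <- check_term(terms[[1]], a_row)
    if (!is.finite(k_fwd) || k_fwd <= 0)
      stop(sprintf("reaction '%s': rate constant missing or non-positive", rid),
           call. = FALSE)
    rows_A[[length(rows_A) + 1]] <- a_row
    rows_B[[length(rows_B) + 1]] <- b_row
    ks <- c(ks, k_fwd)
    if (length(terms) == 2) {
      k_bwd <- check_term(terms[[2]], b_row)
      if (!is.finite(k_bwd) || k_bwd <= 0)
        stop(sprintf("reaction '%s': backward rate constant missing or non-positive",
                     rid), call. = FALSE)
      rows_A[[length(rows_A) + 1]] <- b_row
      rows_B[[length(rows_B) + 1]] <- a_row
      ks <- c(ks, k_bwd)
    }
  }
  rbm(do.call(rbind, rows_A), do.call(rbind, rows_B), ks, x0,
      species = sp_id)
}

# Parse a MathML expression restricted to the mass-action subset:
# products of <ci> factors and <power> applications with integer <cn>
# exponents, numeric <cn> factors folded into nothing (rejected: they
# would change the constant), and at top level optionally <minus> of two
# such products (reversible law). Returns a list of one or two terms,
# each a list(ci = character identifiers, pow = named exponents).
parse_mass_action_math <- function(node, rid) {
  unsupported <- function()
    stop(sprintf("unsupported (non-mass-action) kinetic law in reaction '%s'",
                 rid), call. = FALSE)
  parse_term <- function(nd) {
    name <- xml2::xml_name(nd)
    if (name == "ci") {
      return(list(ci = trimws(xml2::xml_text(nd)), pow = list()))
    }
    if (name != "apply") unsupported()
    children <- xml2::xml_find_all(nd, "./*")
    op <- xml2::xml_name(children[[1]])
    args <- children[-1]
    if (op == "times") {
      out <- list(ci = character(0), pow = list())
      for (arg in args) {
        sub <- parse_term(arg)
        out$ci <- c(out$ci, sub$ci)
        out$pow <- c(out$pow, sub$pow)
      }
      return(out)
    }
    if (op == "power") {
      base <- args[[1]]; expo <- args[[2]]
      if (xml2::xml_name(base) != "ci" || xml2::xml_name(expo) != "cn")
        unsupported()
      id <- trimws(xml2::xml_text(base))
      p <- as.numeric(xml2::xml_text(expo))
      if (is.na(p) || p != round(p) || p < 1) unsupported()
      pw <- list(p); names(pw) <- id
      return(list(ci = id, pow = pw))
    }
    unsupported()
  }
  name <- xml2::xml_name(node)
  if (name == "apply") {
    children <- xml2::xml_find_all(node, "./*")
    if (xml2::xml_name(children[[1]]) == "minus" && length(children) == 3) {
      return(list(parse_term(children[[2]]), parse_term(children[[3]])))
    }
  }
  list(parse_term(node))
}
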