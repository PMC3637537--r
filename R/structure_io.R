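#' Read a protein structure as ordered C-alpha records
#'
#' Parses a PDB file into a C-alpha-only structure. Multi-chain files are
#' concatenated in file order with recorded continuity breaks; only the first
#' alternate location of each residue is kept; HETATM records are ignored.
#' A continuity break is recorded at every chain change, at every gap in
#' author residue numbering, and wherever consecutive C-alpha atoms are more
#' than 4.5 Angstrom apart.
#'
#' @param path path to a PDB file.
#' @param chain_filter optional character vector of chain identifiers to keep.
#' @param model_index 1-based MODEL number to read from multi-model files.
#' @return An object of class `protein_ca`: a list with `atoms` (data frame of
#'   chain, resno, insert, resid, x, y, z), `xyz` (n x 3 matrix), `breaks`
#'   (sorted 1-based indices of the first residue of each continuous stretch,
#'   always starting with 1), and `label`.
#' @export
read_structure <- function(path, chain_filter = NULL, model_index = 1L) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 0L) {
    if (model_index > length(model_starts)) {
      stop("requested model ", model_index, " but file has only ",
           length(model_starts), " model(s)")
    }
    ends <- grep("^ENDMDL", lines)
    from <- model_starts[model_index]
    to <- ends[ends > from][1]
    if (is.na(to)) to <- length(lines)
    lines <- lines[(from + 1L):(to - 1L)]
  } else if (model_index != 1L) {
    stop("requested model ", model_index, " but file has a single model")
  }

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) > 0L) {
    at$insert[is.na(at$insert)] <- ""
    at$chain[is.na(at$chain)] <- ""
    # first alternate location only
    key <- paste(at$chain, at$resno, at$insert, sep = "\r")
    at <- at[!duplicated(key), , drop = FALSE]
  }
  if (!is.null(chain_filter)) {
    missing_chains <- setdiff(chain_filter, unique(at$chain))
    if (length(missing_chains) > 0L) {
      stop("requested chain(s) absent from file: ",
           paste(missing_chains, collapse = ", "))
    }
    at <- at[at$chain %in% chain_filter, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no C-alpha atoms found in ", path)

  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = at$resid, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  new_protein_ca(atoms, label = basename(path))
}

#' Construct a `protein_ca` structure from a C-alpha table
#'
#' @param atoms data frame with columns chain, resno, insert, resid, x, y, z.
#' @param label text label for reports.
#' @param breaks optional explicit stretch starts; if `NULL` they are derived
#'   from chain changes, numbering gaps and C-alpha distances > 4.5 Angstrom.
#' @return `protein_ca` object.
#' @export
new_protein_ca <- function(atoms, label = "structure", breaks = NULL) {
  stopifnot(all(c("chain", "resno", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$resid)) atoms$resid <- "ALA"
  xyz <- unname(cbind(atoms$x, atoms$y, atoms$z))
  if (any(!is.finite(xyz))) stop("non-finite C-alpha coordinates")
  n <- nrow(atoms)
  if (is.null(breaks)) {
    breaks <- 1L
    if (n > 1L) {
      dce <- sqrt(rowSums((xyz[-1L, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
      dres <- diff(atoms$resno)
      newchain <- atoms$chain[-1L] != atoms$chain[-n]
      gap <- newchain | !(dres %in% c(0L, 1L)) | dce > 4.5
      breaks <- c(1L, which(gap) + 1L)
    }
  }
  structure(list(atoms = atoms, xyz = xyz,
                 breaks = sort(unique(as.integer(breaks))), label = label),
            class = "protein_ca")
}

#' @export
print.protein_ca <- function(x, ...) {
  cat(sprintf("protein_ca '%s': %d residues, %d continuous stretch(es), chains: %s\n",
              x$label, nrow(x$atoms), length(x$breaks),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a `protein_ca`.
#' @return integer residue count.
#' @export
n_residues <- function(structure) nrow(structure$atoms)

# 1-based stretch id per residue; residues in the same continuous stretch
# share an id.
stretch_id <- function(structure) {
  n <- n_residues(structure)
  ids <- integer(n)
  ids[structure$breaks] <- 1L
  cumsum(ids)
}

# logical vector: TRUE where a residue starts a new continuous stretch
stretch_start <- function(structure) {
  out <- logical(n_residues(structure))
  out[structure$breaks] <- TRUE
  out
}

format_atom_line <- function(serial, atoms, i, xyz) {
  sprintf("ATOM  %5d  CA  %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, substr(atoms$resid[i], 1, 3),
          substr(paste0(atoms$chain[i], " "), 1, 1), atoms$resno[i],
          substr(paste0(atoms$insert[i], " "), 1, 1),
          xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.0, 0.0)
}

structure_pdb_lines <- function(structure, xyz = structure$xyz,
                                ter_at_breaks = FALSE) {
  n <- n_residues(structure)
  starts <- stretch_start(structure)
  out <- character(0)
  serial <- 0L
  for (i in seq_len(n)) {
    if (ter_at_breaks && i > 1L && starts[i]) out <- c(out, "TER")
    serial <- serial + 1L
    out <- c(out, format_atom_line(serial, structure$atoms, i, xyz))
  }
  c(out, "TER")
}

#' Write a structure as a C-alpha PDB file
#'
#' @param structure a `protein_ca`.
#' @param path output path.
#' @param ter_at_breaks write a TER record at every continuity break.
#' @export
write_structure <- function(structure, path, ter_at_breaks = FALSE) {
  writeLines(c(structure_pdb_lines(structure, ter_at_breaks = ter_at_breaks),
               "END"), path)
  invisible(path)
}

#' Write a superposed structure pair as a two-model PDB file
#'
#' MODEL 1 holds the query unchanged; MODEL 2 holds the model structure with
#' its coordinates transformed by `sup`. The file round-trips through
#' [read_structure()] (with `model_index` 1 or 2) to within PDB coordinate
#' precision (1e-3 Angstrom).
#'
#' @param query,model `protein_ca` structures.
#' @param sup `superposition` mapping model coordinates into the query frame.
#' @param path output path.
#' @export
write_superposed_pair <- function(query, model, sup, path) {
  moved <- apply_superposition(model$xyz, sup)
  lines <- c("MODEL     1",
             structure_pdb_lines(query),
             "ENDMDL",
             "MODEL     2",
             structure_pdb_lines(model, xyz = moved),
             "ENDMDL",
             "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a superposition as plain text
#'
#' Emits the 3x3 rotation matrix (one row per line) followed by the
#' translation vector.
#'
#' @param sup a `superposition`.
#' @param path output path.
#' @export
write_superposition <- function(sup, path) {
  lines <- c("# rotation matrix (rows), then translation (Angstrom); model -> query",
             apply(sup$rotation, 1, function(r) paste(sprintf("%.9f", r), collapse = " ")),
             paste(sprintf("%.9f", sup$translation), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
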