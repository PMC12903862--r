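#' Write systems as (multi-frame, extended) XYZ
#'
#' Periodic systems get an extended-XYZ `Lattice="..."` comment line so the
#' box round-trips.
#'
#' @param systems an [alchemical_system()] or a list of them (frames)
#' @param path output path
#' @param comment base comment string
#' @return `path`, invisibly
#' @export
write_xyz <- function(systems, path, comment = "") {
  if (inherits(systems, "alchemical_system")) systems <- list(systems)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  for (fr in systems) {
    n <- nrow(fr$positions)
    cmt <- comment
    if (!is.null(fr$box))
      cmt <- sprintf('Lattice="%s" %s',
                     paste(sprintf("%.17g", t(fr$box)), collapse = " "), cmt)
    writeLines(c(as.character(n), trimws(cmt)), con)
    writeLines(sprintf("%s %.17g %.17g %.17g", fr$species,
                       fr$positions[, 1], fr$positions[, 2],
                       fr$positions[, 3]), con)
  }
  invisible(path)
}

#' Read (multi-frame, extended) XYZ coordinates
#'
#' @param path input path
#' @param solute solute atom indices to attach to every frame
#' @param lambda coupling parameter to attach
#' @return list of [alchemical_system()] frames (a single frame is still a
#'   length-1 list)
#' @export
read_xyz <- function(path, solute = integer(0), lambda = 1) {
  lines <- readLines(path)
  frames <- list(); i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    cmt <- lines[i + 1L]
    box <- NULL
    m <- regmatches(cmt, regexpr('Lattice="[^"]*"', cmt))
    if (length(m)) {
      vals <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", m),
                                  "\\s+")[[1]])
      box <- matrix(vals, 3L, 3L, byrow = TRUE)
    }
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    species <- vapply(rows, `[[`, character(1), 1L)
    pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <-
      alchemical_system(pos, species, solute = solute, lambda = lambda,
                        box = box)
    i <- i + 2L + n
  }
  frames
}

#' Read a PDB file into an alchemical system
#'
#' Uses the bio3d package when available; the solute can be selected by
#' residue name or by explicit atom indices.
#'
#' @param path PDB file path
#' @param solute_resname residue name(s) marking the solute, or `NULL`
#' @param solute explicit solute atom indices (overrides `solute_resname`)
#' @param lambda coupling parameter
#' @return an [alchemical_system()]
#' @export
read_pdb_system <- function(path, solute_resname = NULL,
                            solute = integer(0), lambda = 1) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  pos <- matrix(pdb$xyz[1, ], ncol = 3L, byrow = TRUE)
  species <- trimws(pdb$atom$elesy)
  species[!nzchar(species)] <- substr(trimws(pdb$atom$elety[!nzchar(species)]),
                                      1L, 1L)
  if (!length(solute) && !is.null(solute_resname))
    solute <- which(pdb$atom$resid %in% solute_resname)
  alchemical_system(pos, species, solute = solute, lambda = lambda)
}
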