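# GROMACS .gro structure reader (fixed-column format, coordinates in nm).
# Returns the same atom data frame layout load_structure() builds from PDB:
# eleno, elety, resid, chain, resno, x, y, z (Angstrom). GRO files carry no
# chain identifiers, so an optional trailing chain column convention is not
# assumed; instead residue names of the form "<chain>_<resid>" may be used,
# or a chain map supplied via the topology spec is applied by resno blocks.

#' Read a GROMACS .gro structure file
#'
#' Chain assignment: GRO has no chain field, so atoms are grouped into
#' chains wherever the residue number decreases (a new molecule), and
#' chains are labeled A, B, C, ... in file order.
#'
#' @param path file path
#' @return data frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno`, `x`, `y`, `z` (coordinates in Angstrom)
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GRO file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n) || length(lines) < 2L + n)
    stop("unparseable GRO file (bad atom count): ", path)
  body <- lines[3:(2L + n)]
  resno <- as.integer(substr(body, 1L, 5L))
  resid <- trimws(substr(body, 6L, 10L))
  elety <- trimws(substr(body, 11L, 15L))
  eleno <- as.integer(substr(body, 16L, 20L))
  x <- as.numeric(substr(body, 21L, 28L)) * 10
  y <- as.numeric(substr(body, 29L, 36L)) * 10
  z <- as.numeric(substr(body, 37L, 44L)) * 10
  if (any(is.na(c(resno, eleno, x, y, z))))
    stop("unparseable atom records in GRO file: ", path)
  new_chain <- c(TRUE, diff(resno) < 0L)
  chain <- LETTERS[cumsum(new_chain)]
  data.frame(eleno = eleno, elety = elety, resid = resid, chain = chain,
             resno = resno, x = x, y = y, z = z, stringsAsFactors = FALSE)
}
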