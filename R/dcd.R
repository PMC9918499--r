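# Minimal CHARMM-format DCD trajectory writer. bio3d reads DCD but does
# not write it; this writer emits the fixed-record binary layout that
# bio3d::read.dcd (and CHARMM/NAMD tools) accept: a CORD header block with
# the icntrl integers (version 24, no unit cell, no fixed atoms), a title
# block, the atom count, then per frame three float records (x, y, z).

#' Write an ensemble as a DCD trajectory
#'
#' @param ensemble [ensemble()] (or plain matrix `n_frames x 3*n_atoms`)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_dcd <- function(ensemble, path) {
  xyz <- if (is.matrix(ensemble)) ensemble else ensemble$xyz
  nf <- nrow(xyz)
  natom <- ncol(xyz) %/% 3L
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: payload length, payload, payload length
    raw <- writer()
    writeBin(length(raw), con, size = 4L)
    writeBin(raw, con)
    writeBin(length(raw), con, size = 4L)
  }
  icntrl <- integer(20L)
  icntrl[1L] <- nf        # NSET
  icntrl[2L] <- 1L        # ISTART
  icntrl[3L] <- 1L        # NSAVC
  icntrl[4L] <- nf        # NSTEP
  icntrl[20L] <- 24L      # CHARMM version flag
  hdr <- c(charToRaw("CORD"),
           writeBin(icntrl, raw(), size = 4L))
  writeBin(84L, con, size = 4L)
  writeBin(hdr, con)
  writeBin(84L, con, size = 4L)
  title <- sprintf("%-80s", "Created by nucdyn write_dcd")
  rec(function() c(writeBin(1L, raw(), size = 4L),
                   charToRaw(title)[1:80]))
  rec(function() writeBin(natom, raw(), size = 4L))
  ix <- 3L * (seq_len(natom) - 1L)
  for (f in seq_len(nf)) {
    fr <- xyz[f, ]
    for (d in 1:3) {
      v <- fr[ix + d]
      rec(function() writeBin(as.numeric(v), raw(), size = 4L))
    }
  }
  invisible(path)
}
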