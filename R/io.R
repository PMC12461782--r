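## Plain-text interchange formats:
##   - COLVAR-style trajectories: "#! FIELDS time lig_coord wat_coord"
##     header, whitespace columns, time in ps;
##   - free-energy grids: "# axis <name> <min> <binwidth> <nbins>" headers
##     plus one value per line in column order with the ligand axis
##     fastest-varying; unvisited cells are written as "inf";
##   - species-level tables: delimited columns species, n_lig,
##     delta_g_kj_mol, sigma_kj_mol.

#' Read a COLVAR-style coordination trajectory
#'
#' @param path file with a `#! FIELDS time lig_coord wat_coord` header and
#'   whitespace-delimited columns.  Time must be strictly increasing and
#'   evenly spaced.
#' @return List with `dt` (ps), `frames` (n x 2 matrix), `time`.
#' @export
readColvar <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#!"))
    stop("missing '#! FIELDS' header line in ", path)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s*", "", lines[1]), "\\s+")[[1]]
  need <- c("time", "lig_coord", "wat_coord")
  missing <- setdiff(need, fields)
  if (length(missing))
    stop("COLVAR header lacks field(s): ", paste(missing, collapse = ", "))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  dat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  colnames(dat) <- fields[seq_len(ncol(dat))]
  tm <- dat[, "time"]
  bad <- which(diff(tm) <= 0)
  if (length(bad))
    stop("non-monotonic time at data line ", bad[1] + 1L, " of ", path)
  list(dt = if (length(tm) > 1) tm[2] - tm[1] else NA_real_,
       frames = dat[, c("lig_coord", "wat_coord"), drop = FALSE],
       time = tm)
}

#' Write a COLVAR-style trajectory
#'
#' @param traj list with `dt` and `frames` (as from [simulateCTMC()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeColvar <- function(traj, path) {
  tm <- (seq_len(nrow(traj$frames)) - 1L) * traj$dt
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time lig_coord wat_coord", con)
  writeLines(sprintf("%.6f %.10g %.10g", tm,
                     traj$frames[, 1], traj$frames[, 2]), con)
  invisible(path)
}

#' Read a free-energy surface grid
#'
#' @param path text grid: two `# axis <name> <min> <binwidth> <nbins>`
#'   header lines (ligand axis first), optional `# temperature <K>`, then
#'   one value per line with the ligand axis fastest-varying; `inf` marks
#'   unvisited cells.
#' @return A [FreeEnergySurface-class].
#' @export
readFesGrid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  axes <- hdr[grepl("^#\\s*axis\\s", hdr)]
  if (length(axes) != 2) stop("expected two '# axis' header lines in ", path)
  parseAxis <- function(h) {
    p <- strsplit(trimws(sub("^#\\s*axis\\s*", "", h)), "\\s+")[[1]]
    list(name = p[1], min = as.numeric(p[2]),
         width = as.numeric(p[3]), n = as.integer(p[4]))
  }
  a1 <- parseAxis(axes[1]); a2 <- parseAxis(axes[2])
  tempLine <- hdr[grepl("^#\\s*temperature\\s", hdr)]
  temperature <- if (length(tempLine))
    as.numeric(sub("^#\\s*temperature\\s*", "", tempLine[1])) else 300
  body <- trimws(lines[!startsWith(lines, "#")])
  body <- body[nzchar(body)]
  vals <- suppressWarnings(as.numeric(sub("^inf$", "Inf", body)))
  if (length(vals) != a1$n * a2$n)
    stop("grid shape mismatch: ", length(vals), " values for ",
         a1$n, " x ", a2$n, " grid")
  if (!any(is.finite(vals))) stop("no visited cells in ", path)
  FreeEnergySurface(matrix(vals, a1$n, a2$n),   # lig fastest-varying
                    axisLig = a1$min + a1$width * (seq_len(a1$n) - 1L),
                    axisWat = a2$min + a2$width * (seq_len(a2$n) - 1L),
                    temperature = temperature)
}

#' Write a free-energy surface grid
#'
#' @param fes a [FreeEnergySurface-class]; axes must be evenly spaced.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFesGrid <- function(fes, path) {
  step <- function(ax) if (length(ax) > 1) ax[2] - ax[1] else 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# axis lig %.10g %.10g %d", fes@axisLig[1], step(fes@axisLig),
            length(fes@axisLig)),
    sprintf("# axis wat %.10g %.10g %d", fes@axisWat[1], step(fes@axisWat),
            length(fes@axisWat)),
    sprintf("# temperature %.10g", fes@temperature)), con)
  v <- as.vector(fes@values)
  out <- ifelse(is.finite(v), sprintf("%.10g", v), "inf")
  writeLines(out, con)
  invisible(path)
}

#' Read or write a species-level table
#'
#' Delimited table with columns `species`, `n_lig`, `delta_g_kj_mol`,
#' `sigma_kj_mol`.
#'
#' @param path file path.
#' @return [SpeciesLevels-class] (read) or `path` invisibly (write).
#' @export
readLevels <- function(path) {
  d <- read.table(path, header = TRUE)
  need <- c("species", "n_lig", "delta_g_kj_mol", "sigma_kj_mol")
  if (!all(need %in% names(d)))
    stop("levels table needs columns: ", paste(need, collapse = ", "))
  SpeciesLevels(d$delta_g_kj_mol, nLig = d$n_lig, sigma = d$sigma_kj_mol,
                species = d$species)
}

#' @rdname readLevels
#' @param levels a [SpeciesLevels-class].
#' @export
writeLevels <- function(levels, path) {
  write.table(data.frame(species = levels@species, n_lig = levels@nLig,
                         delta_g_kj_mol = levels@deltaG,
                         sigma_kj_mol = levels@sigma),
              path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
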