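PARTICLE_COLUMNS <- c("id", "x", "y", "z", "rot", "tilt", "psi",
                      "face", "halfset", "score")

#' Construct / validate a particle table
#'
#' One row per picked particle: voxel position `(x, y, z)` in the tomogram,
#' intrinsic ZYZ orientation `(rot, tilt, psi)` in degrees mapping the
#' reference into the particle, membrane face (`"up"` or `"down"`), an
#' optional gold-standard half-set label (`"A"`/`"B"`, `NA` before
#' assignment) and a correlation score.  Ground-truth and refined tables
#' share this schema.
#'
#' @param df data frame with columns
#'   `id, x, y, z, rot, tilt, psi, face, halfset, score`.
#' @return Validated data frame of class `particle_table`.
#' @export
particle_table <- function(df) {
  missing_cols <- setdiff(PARTICLE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("particle table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df <- df[PARTICLE_COLUMNS]
  if (anyDuplicated(df$id))
    stop("particle table schema error: ids must be unique")
  if (nrow(df) && !all(df$face %in% c("up", "down")))
    stop("particle table schema error: face must be 'up' or 'down'")
  if (nrow(df) && !all(is.na(df$halfset) | df$halfset %in% c("A", "B")))
    stop("particle table schema error: halfset must be 'A', 'B' or NA")
  df$face <- as.character(df$face)
  df$halfset <- as.character(df$halfset)
  class(df) <- c("particle_table", "data.frame")
  df
}

#' @rdname particle_table
#' @export
empty_particle_table <- function() {
  particle_table(data.frame(id = integer(), x = numeric(), y = numeric(),
                            z = numeric(), rot = numeric(), tilt = numeric(),
                            psi = numeric(), face = character(),
                            halfset = character(), score = numeric(),
                            stringsAsFactors = FALSE))
}

#' Per-row rigid transform of a particle table
#'
#' @param table a [particle_table()].
#' @param i row index.
#' @return The [rigid_transform()] of row `i` (zero shift: positions carry
#'   the translation).
#' @export
particle_transform <- function(table, i) {
  rigid_transform(table$rot[i], table$tilt[i], table$psi[i])
}

#' Write a particle table as TSV
#'
#' Tab-separated text with a fixed header; angles and positions printed
#' with 6 decimals so a write/read roundtrip preserves all fields to print
#' precision.
#'
#' @param table a [particle_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_particles <- function(table, path) {
  table <- particle_table(as.data.frame(table))
  out <- as.data.frame(table)
  for (cc in c("x", "y", "z", "rot", "tilt", "psi", "score"))
    out[[cc]] <- sprintf("%.6f", out[[cc]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a particle table from TSV
#'
#' @param path file written by [write_particles()].
#' @return A [particle_table()].
#' @export
read_particles <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(id = "integer", face = "character",
                                  halfset = "character"))
  particle_table(df)
}

#' Write a particle table in a minimal STAR dialect
#'
#' Single `data_particles` block with one `loop_` over the ten schema
#' columns.
#'
#' @param table a [particle_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_particles_star <- function(table, path) {
  table <- particle_table(as.data.frame(table))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_particles", "", "loop_"), con)
  writeLines(sprintf("_crystomo%s%s #%d",
                     toupper(substring(PARTICLE_COLUMNS, 1, 1)),
                     substring(PARTICLE_COLUMNS, 2),
                     seq_along(PARTICLE_COLUMNS)), con)
  if (nrow(table)) {
    rows <- apply(as.data.frame(table), 1, function(r)
      paste(trimws(r), collapse = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

# Positions (n x 3, columns x/y/z, voxels) as a matrix.
particle_positions <- function(table) {
  cbind(x = table$x, y = table$y, z = table$z)
}

# Rotation matrices as a list.
particle_matrices <- function(table) {
  lapply(seq_len(nrow(table)), function(i)
    transform_matrix(c(table$rot[i], table$tilt[i], table$psi[i])))
}
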