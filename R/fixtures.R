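# Small deterministic worked fixtures shared by examples and tests, each
# bundled with its hand-derived expected output.

#' Worked fixtures with embedded expected outputs
#'
#' Returns the small deterministic fixtures used across the package:
#'
#' * `glrlm`: the 4 x 4 two-runs-per-row image with its 0-degree run-length
#'   matrix entries, run count, and hand-computed SHE/GLNU values.
#' * `frat_impulse`: a 3 x 3 single-impulse image; every finite Radon
#'   direction sees exactly one nonzero offset of value 1.
#' * `eltp_patch`: the 8-neighbour patch with `ace = 6`, `we = 1` and its
#'   ternary codes.
#' * `morph_speck_block`: a 20 x 20 mask holding a 1-pixel speck and a
#'   10 x 10 block (opening removes the speck), and `morph_hole`: a block
#'   with a single interior hole pixel (closing fills it).
#'
#' @return a named list of fixtures; each element is a list holding the input
#'   and its expected outputs.
#' @export
worked_fixtures <- function() {
  glrlm_img <- rbind(c(0, 0, 1, 1),
                     c(0, 0, 1, 1),
                     c(2, 2, 2, 2),
                     c(3, 3, 3, 3))
  impulse <- matrix(0, 3, 3); impulse[1, 1] <- 1
  speck_block <- matrix(FALSE, 20, 20)
  speck_block[3, 3] <- TRUE
  speck_block[8:17, 8:17] <- TRUE
  hole <- matrix(FALSE, 12, 12)
  hole[4:9, 4:9] <- TRUE
  hole[6, 6] <- FALSE
  list(
    glrlm = list(
      image = glrlm_img, gray_bins = 4, levels = 4,
      # 0 degrees: runs (0,2) x2, (1,2) x2, (2,4) x1, (3,4) x1
      expected_entries = list(c(gray = 0, length = 2, count = 2),
                              c(gray = 1, length = 2, count = 2),
                              c(gray = 2, length = 4, count = 1),
                              c(gray = 3, length = 4, count = 1)),
      num_runs = 6, she = 0.1875, glnu = 10 / 6
    ),
    frat_impulse = list(
      image = impulse, p = 3,
      nonzero_per_direction = 1, value = 1
    ),
    eltp_patch = list(
      neighbors = c(10, 2, 6, 6, 6, 6, 6, 6), ace = 6, we = 1,
      codes = c(1L, -1L, 0L, 0L, 0L, 0L, 0L, 0L)
    ),
    morph_speck_block = list(
      mask = speck_block, speck = c(3, 3), block = c(8, 17)
    ),
    morph_hole = list(
      mask = hole, hole = c(6, 6)
    )
  )
}
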