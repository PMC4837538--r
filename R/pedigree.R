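# Pedigree simulation for a closed multigenerational line.

#' Default generation sizes of the study population
#'
#' Numbers of males and females per generation (G1..G7) of the
#' seven-generation closed Duroc line the package emulates: 836 animals in
#' total, 368 males and 468 females. The `castrate` column gives the number
#' of sib-tested males (barrows), which are excluded from breeding.
#'
#' @return data.frame with columns `male`, `female`, `castrate`.
#' @examples
#' sum(defaultGenerationSizes()$male + defaultGenerationSizes()$female) # 836
#' @export
defaultGenerationSizes <- function() {
  data.frame(
    male     = c(16L, 19L, 42L, 67L, 73L, 71L, 80L),
    female   = c(22L, 40L, 47L, 86L, 86L, 86L, 101L),
    castrate = c(0L, 10L, 19L, 31L, 40L, 39L, 44L))
}

#' Generate a closed-line pedigree
#'
#' Builds a multigenerational pedigree under inbreeding-avoidant random
#' mating: in every non-founder generation each dam of the previous
#' generation is assigned one sire (full-sib and parent-offspring matings
#' are avoided whenever an alternative sire exists; castrates never breed),
#' and offspring are allotted to dams uniformly at random, so litters are
#' approximately even. Sexes are assigned to match the requested counts.
#'
#' @param generationSizes data.frame with columns `male` and `female`
#'   (optionally `castrate`, a sub-count of `male`), one row per generation;
#'   defaults to [defaultGenerationSizes()].
#' @param founderGenerations Number of initial generations treated as
#'   founders (both parents unknown); 1 or 2.
#' @param seed Integer seed.
#' @return A [Pedigree-class] with `sum(male + female)` animals.
#' @examples
#' ped <- generatePedigree(data.frame(male = c(2, 3), female = c(4, 5)), seed = 1)
#' length(ped)  # 14
#' @export
generatePedigree <- function(generationSizes = defaultGenerationSizes(),
                             founderGenerations = 1L, seed = NULL) {
  gs <- as.data.frame(generationSizes)
  if (nrow(gs) < 1L) stop("'generationSizes' must be non-empty")
  if (!all(c("male", "female") %in% names(gs)))
    stop("'generationSizes' needs columns 'male' and 'female'")
  if (is.null(gs$castrate)) gs$castrate <- 0L
  if (any(gs$castrate > gs$male)) stop("castrate count exceeds male count")
  founderGenerations <- as.integer(founderGenerations)
  if (!founderGenerations %in% c(1L, 2L)) stop("'founderGenerations' must be 1 or 2")
  nonTerminal <- seq_len(nrow(gs) - 1L)
  if (any(gs$male[nonTerminal] - gs$castrate[nonTerminal] <= 0L) && nrow(gs) > founderGenerations)
    stop("every non-terminal generation needs at least one intact male")
  if (any(gs$female[nonTerminal] <= 0L) && nrow(gs) > founderGenerations)
    stop("every non-terminal generation needs at least one female")

  withSeed(seed, {
    id <- sire <- dam <- sex <- character(0)
    gen <- integer(0)
    sire_of <- dam_of <- character(0)  # parallel lookup for full-sib checks
    names_prev_m <- names_prev_f <- character(0)
    parent <- list()  # id -> c(sire, dam)
    for (g in seq_len(nrow(gs))) {
      nm <- gs$male[g]; nf <- gs$female[g]; nc <- gs$castrate[g]
      n <- nm + nf
      ids <- sprintf("G%d_%03d", g, seq_len(n))
      sx <- c(rep("male", nm), rep("female", nf))
      if (nc > 0L) sx[sample.int(nm, nc)] <- "castrate"
      sx <- sample(sx)  # shuffle order within generation
      if (g <= founderGenerations) {
        s <- rep(NA_character_, n); d <- rep(NA_character_, n)
      } else {
        dams <- names_prev_f
        sires_avail <- names_prev_m
        if (!length(sires_avail)) stop("no intact males available in generation ", g - 1L)
        # one sire per dam, avoiding full-sib pairs when alternatives exist
        mate <- character(length(dams))
        for (i in seq_along(dams)) {
          dp <- parent[[dams[i]]]
          ok <- vapply(sires_avail, function(sv) {
            sp <- parent[[sv]]
            if (is.null(sp) || is.null(dp)) return(TRUE)
            !(identical(sp[1], dp[1]) && identical(sp[2], dp[2]) &&
                !is.na(sp[1]) && !is.na(sp[2]))
          }, logical(1))
          pool <- if (any(ok)) sires_avail[ok] else sires_avail
          mate[i] <- pool[sample.int(length(pool), 1L)]
        }
        litter <- sample.int(length(dams), n, replace = TRUE)
        d <- dams[litter]
        s <- mate[litter]
      }
      for (i in seq_len(n)) parent[[ids[i]]] <- c(s[i], d[i])
      id <- c(id, ids); sire <- c(sire, s); dam <- c(dam, d)
      sex <- c(sex, sx); gen <- c(gen, rep(g, n))
      names_prev_m <- ids[sx == "male"]
      names_prev_f <- ids[sx == "female"]
    }
    Pedigree(id = id, sire = sire, dam = dam, sex = sex, generation = gen)
  })
}
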