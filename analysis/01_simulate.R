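#!/usr/bin/env Rscript

# Stage 1: simulate the synthetic study.
#
# Generates the breeding-design pedigree and covariates (about 180
# phenotyped hatchlings from ~39 dams over two seasons, split-clutch
# thermal treatments, dummy sires for wild-conceived clutches), draws
# latent brightness / elongation / contrast values under the published
# coefficient estimates with heritabilities 0.16 / 0.18 / 0.23, and
# renders one dorsal swatch per individual. Everything lands under
# results/synthetic_study/.

suppressPackageStartupMessages(library(dragoncolour))

out <- "results/synthetic_study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20150901L
seeds <- make_subseeds(seed, 2L)

cfg <- breeding_config(seed = seeds[1])
sim <- simulate_pedigree(cfg)
records <- simulate_records(sim$pedigree, sim$covariates, default_truth(),
                            seed = seeds[1])
images <- render_study_swatches(records, seed = seeds[2],
                                image_height = 60L, image_width = 40L)

img_dir <- file.path(out, "swatches")
dir.create(img_dir, showWarnings = FALSE)
for (id in names(images)) {
  write_swatch_png(images[[id]], file.path(img_dir, paste0(id, ".png")))
}
write.csv(sim$pedigree, file.path(out, "pedigree.csv"), row.names = FALSE)
write.csv(sim$covariates, file.path(out, "covariates.csv"), row.names = FALSE)
write.csv(records, file.path(out, "latent_traits.csv"), row.names = FALSE)

cat(sprintf("simulated %d offspring from %d dams (%d parental cage-seasons, %d rearing cages)\n",
            nrow(sim$covariates), length(unique(sim$covariates$dam)),
            length(unique(sim$covariates$parental_cage)),
            length(unique(sim$covariates$offspring_cage))))
cat(sprintf("wrote pedigree (%d individuals), covariates, latent traits and %d swatches to %s\n",
            nrow(sim$pedigree), length(images), out))
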