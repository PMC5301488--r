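#!/usr/bin/env Rscript
# Figures for the phantom analysis: depth-density profiles per region
# with labeled plexus peaks, transverse per-plexus profiles, and the
# cross-sectional density map. Requires 03 and 04.

suppressMessages({library(octapr); library(ggplot2); library(data.table)})
out <- "results/05_figures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

regions <- c("peripapillary", "parafoveal", "perifoveal", "peripheral")
profs <- rbindlist(lapply(regions, function(nm) {
  dt <- fread(file.path("results/03_profiles",
                        paste0("depth_profile_", nm, ".csv")))
  dt[, region := factor(nm, levels = regions)]
}))
finds <- fread("results/03_profiles/plexus_findings.csv")
finds <- finds[plexus != "unassigned"]
finds[, region := factor(region, levels = regions)]

p1 <- ggplot(profs, aes(z, density)) +
  geom_line(linewidth = 0.4) +
  geom_point(data = finds, aes(z, height, color = plexus), size = 2) +
  facet_wrap(~region, ncol = 2) +
  labs(x = "normalized depth (voxels)", y = "capillary density",
       color = "plexus",
       title = "Depth-resolved capillary density by region") +
  theme_minimal(base_size = 10)
ggsave(file.path(out, "depth_profiles.png"), p1, width = 7, height = 5,
       dpi = 150)

tp <- fread("results/04_density/transverse_profiles.csv")
p2 <- ggplot(tp[!is.na(density)], aes(ecc_mm, density, color = plexus)) +
  geom_line(linewidth = 0.4) +
  labs(x = "distance from disc edge (mm)", y = "vessel density",
       title = "Transverse vessel density (max projection, large vessels included)") +
  theme_minimal(base_size = 10)
ggsave(file.path(out, "transverse_profiles.png"), p2, width = 7,
       height = 3.5, dpi = 150)

cs <- fread("results/04_density/cross_section_density.csv")
p3 <- ggplot(cs, aes(x_mm, -z_mm, fill = pmin(density, 0.3))) +
  geom_tile() +
  scale_fill_viridis_c(name = "density", option = "inferno") +
  coord_fixed(ratio = 4) +
  labs(x = "x (mm, temporal positive)", y = "-depth (mm)",
       title = "Cross-sectional capillary density (super-voxels)") +
  theme_minimal(base_size = 10)
ggsave(file.path(out, "cross_section_density.png"), p3, width = 8,
       height = 3, dpi = 150)
cat("Wrote", length(list.files(out)), "figures to", out, "\n")
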