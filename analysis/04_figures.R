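#!/usr/bin/env Rscript
# Step 4: diagnostic figures for one representative subject.
#
# Panels mirror the standard presentation of these biomarkers: the VCG
# X component with detected beats, the RR tachogram, the RR power spectrum
# with the LF/HF bands, the deceleration-anchored PRSA curve, the dT-angle
# series before/after median filtering, and the repolarization PRSA curve.

suppressMessages(library(cardiovag))
suppressMessages(library(ggplot2))

f <- "results/cohort/S01_rest.csv"
if (!file.exists(f)) stop("run analysis/01_simulate.R first")
panel <- suppressWarnings(analyze_recording(f, keep_intermediates = TRUE))
ii <- attr(panel, "intermediates")
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

vcg <- ii$vcg
dl <- ii$delineation
tt <- (seq_along(vcg$v_x) - 1) / vcg$fs
seg <- tt <= 10
p1 <- ggplot(data.frame(t = tt[seg], vx = vcg$v_x[seg]), aes(t, vx)) +
  geom_line(linewidth = 0.3) +
  geom_point(data = data.frame(t = (dl$r_indices - 1) / vcg$fs,
                               vx = vcg$v_x[dl$r_indices])[
               (dl$r_indices - 1) / vcg$fs <= 10, ],
             colour = "red", size = 1) +
  labs(x = "time (s)", y = "Vx (uV)", title = "VCG X component, detected R peaks")

p2 <- ggplot(dl$tachogram, aes(t_s, rr_ms, colour = ectopic)) +
  geom_line(colour = "grey60", linewidth = 0.3) + geom_point(size = 0.8) +
  scale_colour_manual(values = c("FALSE" = "black", "TRUE" = "red")) +
  labs(x = "time (s)", y = "RR (ms)", title = "RR tachogram with 20% rule flags")

sp <- ii$spectrum
p3 <- ggplot(data.frame(f = sp$frequencies, psd = sp$psd), aes(f, psd)) +
  geom_area(data = ~subset(.x, f >= 0.04 & f <= 0.15), fill = "steelblue", alpha = 0.5) +
  geom_area(data = ~subset(.x, f >= 0.15 & f <= 0.40), fill = "orange", alpha = 0.5) +
  geom_line() + coord_cartesian(xlim = c(0, 0.5)) +
  labs(x = "frequency (Hz)", y = "PSD (ms2/Hz)",
       title = sprintf("RR spectrum: LF %.0f ms2, HF %.0f ms2", panel$lf, panel$hf))

dcp <- ii$dc_prsa
p4 <- ggplot(data.frame(k = dcp$k, rr = dcp$curve), aes(k, rr)) +
  geom_line() + geom_point(size = 0.8) + geom_vline(xintercept = 0, linetype = 2) +
  labs(x = "beat offset from anchor", y = "RR (ms)",
       title = sprintf("Deceleration PRSA (%d anchors): DC = %.1f ms",
                       dcp$anchor_count, panel$dc))

ang <- ii$angle_series
p5 <- ggplot(ang, aes(t_s)) +
  geom_line(aes(y = dt_raw_deg), colour = "grey70", linewidth = 0.3) +
  geom_line(aes(y = dt_filt_deg), colour = "black") +
  labs(x = "time (s)", y = "dT (deg)",
       title = "T-vector angle series (grey raw, black median-filtered)")

prp <- ii$prd_prsa
p6 <- ggplot(data.frame(k = prp$k, dt = prp$curve), aes(k, dt)) +
  geom_line() + geom_point(size = 0.8) + geom_vline(xintercept = 0, linetype = 2) +
  labs(x = "beat offset from anchor", y = "dT (deg)",
       title = sprintf("Repolarization PRSA (%d anchors): PRD = %.3f deg",
                       prp$anchor_count, panel$prd))

for (nm in paste0("p", 1:6)) {
  ggsave(file.path("results/figures", paste0(nm, ".pdf")), get(nm),
         width = 6, height = 3)
}
cat("wrote 6 figures to results/figures/\n")
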