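# Running the event analysis on ERA5

The packaged generators stand in for reanalysis data; users with access to
the ERA5 archive can run the detection and trend stages on the real fields
as follows.

1. Download *ERA5 hourly data on single levels* (Copernicus Climate Data
   Store, DOI `10.24381/cds.adbb2d47`) for 1950 onwards, variables 2 m (or
   maximum) temperature, total precipitation / rainfall, and snow depth
   (metres of water equivalent), at the native 0.25 degree resolution over
   your Arctic domain.
2. Aggregate hourly to daily outside R (e.g. with `cdo daymax` for
   temperature and `cdo daysum` for rainfall, `cdo daymean` for snow
   depth), and export the daily fields to the package's CSV cube layout
   (`lat, lon, date, tasmax, pr, swe`, one row per cell-day) with any
   NetCDF-to-text tool; pass `snow_unit = "m"` to `read_cube()` so snow
   depth is converted to mm SWE on read.
3. In R:

   ```r
   cube  <- read_cube("era5_daily.csv", snow_unit = "m")
   cube1 <- aggregate_grid(cube, target = 1)          # 0.25 deg -> 1 deg
   thr   <- compute_threshold(cube1, baseline = c(1950, 1980))
   warm  <- detect_warming_events(cube1, thr)
   ros   <- detect_ros_events(cube1)
   sw    <- annual_summaries(warm, cube1)
   paired_period_test(sw, c(1950, 1980), c(1990, 2020))
   ```

4. Regional trends: subset with `subset_cube(cube1, arctic_regions()$yamal)`
   and feed per-season regional means of the summaries to `theil_sen()`;
   winter precipitation trends come from `precip_trends()` (ERA5 snowfall
   goes in as `prsn`).

Memory: a pan-Arctic 1-degree daily cube for 1950-2020 is several GiB as
text; process one region or one decade at a time, or adapt `read_cube()`
to a streaming reader.
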