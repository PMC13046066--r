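element,energy_keV,mu_m_m2_per_kg,source
H,50,0.033550,xcom_grid
H,88,0.030273,xcom_grid_loglog_80_100
C,50,0.018710,xcom_grid
C,88,0.015683,xcom_grid_loglog_80_100
N,50,0.019800,xcom_grid
N,88,0.015921,xcom_grid_loglog_80_100
O,50,0.021320,xcom_grid
O,88,0.016231,xcom_grid_loglog_80_100
Ca,50,0.101900,xcom_grid
Ca,88,0.030820,xcom_grid_loglog_80_100
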