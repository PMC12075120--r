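group,layer,cell_type,C_m,g_L,tau_ref,V_rest,V_th
VIP1,L1,VIP,37.11,4.07,3.5,-65.5,-40.2
E2/3,L2/3,E,123.41,2.47,3,-80.97,-40.53
PV2/3,L2/3,PV,70.95,9.49,1.26,-82.35,-56.32
SST2/3,L2/3,SST,82.34,3.17,1.85,-69.16,-39.95
VIP2/3,L2/3,VIP,41.23,6.4,2.75,-67.94,-41.34
E4,L4,E,80.16,5.16,4.4,-72.53,-47.63
PV4,L4,PV,81.21,9.19,1.5,-70.45,-44.23
SST4,L4,SST,132.86,7.96,2.2,-74.2,-44.07
VIP4,L4,VIP,40.3,1.87,2.4,-63.14,-40.89
E5,L5,E,149.43,16.66,4.25,-68.28,-40.55
PV5,L5,PV,70.9,5.21,1.85,-77.5,-51.2
SST5,L5,SST,52.32,3.43,1.9,-70.01,-47.38
VIP5,L5,VIP,59.29,6.52,2.55,-72,-51.2
E6,L6,E,99.96,5.88,3.3,-77.5,-42.31
PV6,L6,PV,49.65,6.86,1.65,-76.42,-49.06
SST6,L6,SST,96.09,2.99,2.1,-62.99,-37.19
VIP6,L6,VIP,65.87,6.09,2.85,-78.85,-44.81
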