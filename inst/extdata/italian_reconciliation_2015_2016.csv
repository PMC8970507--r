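year,fleet_segment,variable_name,sum_costs_by_metier,costs_by_fleet_segment
2015,DTS_VL1218,fuel_costs,32724856.52,48857605.00
2016,DTS_VL1218,fuel_costs,32939217.59,42962358.00
2015,DTS_VL1218,labour_costs,47387361.97,44073843.00
2016,DTS_VL1218,labour_costs,46853510.47,44856310.00
2015,DTS_VL1824,fuel_costs,41411282.73,59385350.00
2016,DTS_VL1824,fuel_costs,43208396.67,51021250.00
2015,DTS_VL1824,labour_costs,45782917.51,37494387.00
2016,DTS_VL1824,labour_costs,47788448.40,43892592.00
2015,DTS_VL2440,fuel_costs,16699956.82,27161577.00
2016,DTS_VL2440,fuel_costs,18717106.16,25610939.10
2015,DTS_VL2440,labour_costs,27341877.83,28002571.00
2016,DTS_VL2440,labour_costs,26310929.14,27535993.57
2015,HOK_VL1218,fuel_costs,3000661.00,2475812.00
2016,HOK_VL1218,fuel_costs,2519331.00,2445413.00
2015,HOK_VL1218,labour_costs,5355868.54,4140049.00
2016,HOK_VL1218,labour_costs,5361530.78,4018552.00
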