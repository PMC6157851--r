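landscape_state,use_state,ecological_state,strategy
high,high,high,"Recognise and maintain key ecological and landscape elements, and monitor visitor use; consider reactive conservation in most ecologically degraded sites; high potential for citizen engagement in monitoring and maintenance"
high,high,low,"Recognise and maintain key valuable landscape elements; study potential areas of conflicts (e.g. crowding, conflicts between user groups) and ways to mitigate them; potential for engaging the public in ecological restoration"
high,low,high,"Study reasons for low use; aim for spatially limited use e.g. improve access to selected areas with subtle, spatially-concentrated access ways (e.g. duckboards, high walkways); enhance public awareness of the ecological value"
high,low,low,"Study the reasons for low use; use can be encouraged and guided here from other close-by areas to alleviate pressure (potential conflict resolution areas), while maintaining valuable landscape elements; consider regeneration/restoration of ecological value"
low,high,high,"Potential areas of concern; monitor and manage effects of recreational use; high potential for recruitment of users for planning; co-design attractive landscape elements along main routes to encourage visitors to stay on formal paths"
low,high,low,"Study the reasons for low landscape values; high potential for user conflict and conflict resolution; high potential for recruitment of users for co-design"
low,low,high,"Sites with high potential for proactive conservation approaches; natural dynamics and conservation targets could be the main focus of planning and maintenance"
low,low,low,"Potential sites for reconciliation ecology and experimental society; use co-planning and experiments to improve quality"
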